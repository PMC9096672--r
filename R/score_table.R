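#' Point-based score tables
#'
#' A `score_table` is the core container of the package: for each variable it
#' holds an ordered set of category labels and one non-negative integer point
#' value per category. A patient's score is the sum of the matched category
#' points across variables. Continuous variables additionally carry the cut
#' points that map a numeric value to its category; intervals are
#' lower-closed and upper-open, so a value exactly equal to a cut belongs to
#' the interval it opens (q1 <= x < q2).
#'
#' @param variables named list; each element is a list with components
#'   `levels` (character vector of ordered category labels), `points`
#'   (non-negative integers, same length) and optionally `cuts` (strictly
#'   increasing numeric vector with `length(levels) == length(cuts) + 1`)
#'   for continuous variables.
#' @return an object of class `score_table`.
#' @seealso [prosc_table()], [normalize_table()], [apply_score_table()]
#' @export
#' @examples
#' tab <- score_table(list(
#'   rhythm = list(levels = c("unshockable", "shockable"), points = c(0, 30)),
#'   age = list(levels = c("<60", ">=60"), points = c(13, 0), cuts = 60)
#' ))
#' max_score(tab)
score_table <- function(variables) {
  stop_if_not(is.list(variables) && length(variables) >= 1 &&
                !is.null(names(variables)) && all(nzchar(names(variables))),
              "'variables' must be a non-empty named list")
  variables <- lapply(variables, function(v) {
    v$levels <- as.character(v$levels)
    v$points <- as.numeric(v$points)
    if (!is.null(v$cuts)) v$cuts <- as.numeric(v$cuts)
    v[c("levels", "points", if (!is.null(v$cuts)) "cuts")]
  })
  tab <- structure(list(variables = variables), class = "score_table")
  validate_score_table(tab)
  tab
}

#' @rdname score_table
#' @param x,table a `score_table`.
#' @export
validate_score_table <- function(table) {
  stop_if_not(inherits(table, "score_table"), "not a score_table")
  for (nm in names(table$variables)) {
    v <- table$variables[[nm]]
    stop_if_not(length(v$levels) == length(v$points) && length(v$levels) >= 1,
                "variable '", nm, "': levels and points lengths differ")
    stop_if_not(!anyDuplicated(v$levels),
                "variable '", nm, "': duplicated category labels")
    stop_if_not(all(is.finite(v$points)) && all(v$points >= 0) &&
                  all(v$points == round(v$points)),
                "variable '", nm, "': points must be non-negative integers")
    stop_if_not(any(v$points == 0),
                "variable '", nm, "': must have a 0-point reference category")
    if (!is.null(v$cuts)) {
      stop_if_not(length(v$levels) == length(v$cuts) + 1,
                  "variable '", nm, "': need length(levels) == length(cuts) + 1")
      stop_if_not(all(diff(v$cuts) > 0),
                  "variable '", nm, "': cuts must be strictly increasing")
    }
  }
  invisible(table)
}

#' @rdname score_table
#' @export
max_score <- function(table) {
  validate_score_table(table)
  sum(vapply(table$variables, function(v) max(v$points), numeric(1)))
}

#' @export
print.score_table <- function(x, ...) {
  cat("Point-based score table (max ", max_score(x), " points)\n", sep = "")
  df <- as.data.frame(x)
  for (nm in unique(df$variable)) {
    cat("  ", nm, "\n", sep = "")
    sub <- df[df$variable == nm, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-24s %3d\n", sub$category[i], as.integer(sub$points[i])))
    }
  }
  invisible(x)
}

#' @export
#' @rdname score_table
#' @param row.names,optional,... passed through for S3 consistency.
as.data.frame.score_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- do.call(rbind, lapply(names(x$variables), function(nm) {
    v <- x$variables[[nm]]
    data.frame(variable = nm, category = v$levels, points = as.integer(v$points),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rescale a score table to a target maximum
#'
#' Multiplies every point value by `target_max / max_score(table)`, rounds
#' half-away-from-zero to integers, then adjusts the single largest point
#' value by the minimal integer needed so that the maximum attainable total
#' equals `target_max` exactly. Zero-point reference categories stay at zero,
#' and a table already at the target maximum is returned unchanged (the
#' operation is idempotent).
#'
#' @param table a [score_table()].
#' @param target_max positive integer; the desired maximum total (default 100).
#' @return a `score_table` whose `max_score()` equals `target_max`.
#' @export
normalize_table <- function(table, target_max = 100L) {
  validate_score_table(table)
  stop_if_not(length(target_max) == 1 && target_max > 0 &&
                target_max == round(target_max), "target_max must be a positive integer")
  cur <- max_score(table)
  stop_if_not(cur > 0, "cannot normalize an all-zero score table")
  scale <- target_max / cur
  vars <- lapply(table$variables, function(v) {
    v$points <- round_half_away(v$points * scale)
    v
  })
  # post-rounding adjustment: push the residual onto the largest single point
  newmax <- sum(vapply(vars, function(v) max(v$points), numeric(1)))
  resid <- target_max - newmax
  if (resid != 0) {
    allpts <- unlist(lapply(vars, function(v) v$points), use.names = FALSE)
    top <- max(allpts)
    for (nm in names(vars)) {
      i <- which(vars[[nm]]$points == top)
      if (length(i)) {
        vars[[nm]]$points[i[1]] <- vars[[nm]]$points[i[1]] + resid
        break
      }
    }
  }
  score_table(vars)
}

#' Score records with a point table
#'
#' Computes the additive total score for each record: every table variable is
#' matched to the record's value (numerically via the table's cut points for
#' continuous variables, under the q1 <= x < q2 convention; by exact label
#' for categorical variables) and the matched points are summed.
#'
#' @param records data frame with one row per patient; must contain every
#'   variable in the table with non-missing values.
#' @param table a [score_table()].
#' @return integer vector of total scores, one per record.
#' @export
#' @examples
#' rec <- data.frame(age = 55, response_time = 4, first_rhythm = "shockable",
#'                   witnessed = "professional", prehospital_drug = "yes")
#' apply_score_table(rec, prosc_table())  # 100
apply_score_table <- function(records, table) {
  validate_score_table(table)
  stop_if_not(is.data.frame(records), "'records' must be a data frame")
  total <- integer(nrow(records))
  for (nm in names(table$variables)) {
    v <- table$variables[[nm]]
    stop_if_not(nm %in% names(records),
                "scoring error: required field '", nm, "' absent from records")
    x <- records[[nm]]
    stop_if_not(!anyNA(x),
                "scoring error: missing value in required field '", nm, "'")
    if (!is.null(v$cuts)) {
      stop_if_not(is.numeric(x), "scoring error: field '", nm, "' must be numeric")
      idx <- findInterval(x, v$cuts) + 1L  # cuts[i] <= x < cuts[i+1]
    } else {
      idx <- match(as.character(x), v$levels)
      if (anyNA(idx)) {
        bad <- unique(as.character(x)[is.na(idx)])
        stop_if_not(FALSE, "category error: value(s) ", paste(bad, collapse = ", "),
                    " of field '", nm, "' match no category")
      }
    }
    total <- total + as.integer(v$points[idx])
  }
  total
}

#' Read or write a score table as JSON
#'
#' @param table a [score_table()].
#' @param path file path.
#' @return `read_score_table()` returns a `score_table`;
#'   `write_score_table()` returns `path` invisibly.
#' @export
write_score_table <- function(table, path) {
  validate_score_table(table)
  payload <- list(max_score = max_score(table),
                  variables = lapply(table$variables, function(v) {
                    out <- list(levels = v$levels, points = as.integer(v$points))
                    if (!is.null(v$cuts)) out$cuts <- v$cuts
                    out
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- lapply(payload$variables, function(v) {
    v$levels <- as.character(v$levels)
    v$points <- as.numeric(v$points)
    if (!is.null(v$cuts)) v$cuts <- as.numeric(v$cuts)
    v
  })
  score_table(vars)
}
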