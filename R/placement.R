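#' Summarize electrode-placement evaluations
#'
#' Aggregates per-animal, per-placement quality grades into counts and
#' percentages per placement, in the layout of a placement-evaluation
#' table: one column per placement (A, B, C), one row per grade
#' (undetectable, unclear, clear). Percentages use the number of animals
#' evaluated at that placement as the denominator (not every animal is
#' tested at every position) and are rounded half-up to one decimal.
#'
#' @param evals data frame with columns \code{turtle_id},
#'   \code{placement} (A/B/C) and \code{grade}
#'   (undetectable/unclear/clear); at most one row per
#'   (turtle, placement) pair.
#' @return a data frame of class \code{placement_summary} with columns
#'   \code{placement}, \code{grade}, \code{count}, \code{total},
#'   \code{pct}. Empty input yields an empty summary.
#' @export
summarize_placements <- function(evals) {
  grades <- c("undetectable", "unclear", "clear")
  empty <- data.frame(placement = character(0), grade = character(0),
                      count = integer(0), total = integer(0),
                      pct = numeric(0))
  if (!nrow(evals)) {
    class(empty) <- c("placement_summary", "data.frame")
    return(empty)
  }
  stopifnot(all(c("turtle_id", "placement", "grade") %in% names(evals)))
  if (!all(evals$placement %in% PLACEMENTS))
    stop_validation("unknown placement label(s): %s",
                    paste(setdiff(evals$placement, PLACEMENTS), collapse = ", "))
  if (!all(evals$grade %in% grades))
    stop_validation("unknown grade(s): %s",
                    paste(setdiff(evals$grade, grades), collapse = ", "))
  key <- paste(evals$turtle_id, evals$placement)
  if (anyDuplicated(key))
    stop_validation("duplicate evaluation for (turtle, placement): %s",
                    key[duplicated(key)][1])
  placements <- intersect(PLACEMENTS, unique(evals$placement))
  out <- expand.grid(grade = grades, placement = placements,
                     stringsAsFactors = FALSE)[, c("placement", "grade")]
  out$count <- mapply(function(p, g)
    sum(evals$placement == p & evals$grade == g), out$placement, out$grade)
  tot <- tapply(out$count, out$placement, sum)
  out$total <- as.integer(tot[out$placement])
  out$pct <- round_half_up(100 * out$count / out$total, 1)
  rownames(out) <- NULL
  class(out) <- c("placement_summary", "data.frame")
  out
}

#' @export
print.placement_summary <- function(x, ...) {
  if (!nrow(x)) {
    cat("<placement_summary> (no evaluations)\n")
    return(invisible(x))
  }
  placements <- unique(x$placement)
  cat("Evaluation    ", paste(sprintf("  Position %s    ", placements),
                              collapse = ""), "\n", sep = "")
  for (g in unique(x$grade)) {
    row <- x[x$grade == g, ]
    cells <- sprintf("%3d (%5.1f%%)  ", row$count, row$pct)
    cat(sprintf("%-14s", g), paste(cells, collapse = ""), "\n", sep = "")
  }
  tot <- x[!duplicated(x$placement), ]
  cat(sprintf("%-14s", "Total"),
      paste(sprintf("%3d           ", tot$total), collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' Cross-position improvement: unclear at A, clear at C
#'
#' Counts animals graded \code{unclear} at placement A but \code{clear}
#' at placement C (the position with the negative electrode closest to
#' the neck), and expresses the count as a percentage of all study
#' animals. The denominator is supplied by the caller because not every
#' animal is evaluated at both positions.
#'
#' @param evals evaluation data frame as in
#'   \code{\link{summarize_placements}}.
#' @param n_total total number of study animals (> 0).
#' @return list with \code{count} and \code{pct} (one decimal,
#'   half-up rounding).
#' @export
cross_position_improvement <- function(evals, n_total) {
  if (!is_scalar_number(n_total) || n_total <= 0)
    stop_validation("n_total must be a positive count")
  if (!nrow(evals)) return(list(count = 0L, pct = 0))
  at_a <- evals$turtle_id[evals$placement == "A" & evals$grade == "unclear"]
  at_c <- evals$turtle_id[evals$placement == "C" & evals$grade == "clear"]
  count <- length(intersect(at_a, at_c))
  list(count = count, pct = round_half_up(100 * count / n_total, 1))
}

#' Read / write a placement-evaluations file
#'
#' Tab-separated text with a header line and columns \code{turtle_id},
#' \code{placement}, \code{grade}.
#'
#' @param path file path.
#' @export
read_placement_evals <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("turtle_id", "placement", "grade")
  if (!all(need %in% names(ev)))
    stop_validation("%s: expected columns %s", path,
                    paste(need, collapse = ", "))
  ev
}
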