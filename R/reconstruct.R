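#' Reconstruct admissible stage-score vectors from printed group summaries
#'
#' Published group summaries of an ordinal three-stage score (values in
#' {1, 2, 3}) often admit only one or a few per-animal score vectors. This
#' enumerates every multiset in `{1,2,3}^n` whose mean, rounded to the
#' printed precision, matches the printed mean, and ranks the candidates
#' by the absolute difference between their sample SD and the printed SD.
#' Ties in that ranking are reported, never silently broken.
#'
#' @param mean printed group mean.
#' @param sd printed group SD.
#' @param n group size (<= 15).
#' @param digits decimal places of the printed mean/SD (default 1).
#' @return A `score_reconstruction`: list with `candidates` (score vectors
#'   sorted by SD distance, each in decreasing order), `sd` (their sample
#'   SDs), `sd_diff`, and `tie` (TRUE when the best SD distance is shared).
#'   `candidates` is empty when no multiset is admissible.
#' @export
reconstruct_stage_scores <- function(mean, sd, n, digits = 1) {
  if (n > 15) stop("n must be <= 15")
  if (n < 1) stop("n must be >= 1")
  cand <- list(); sds <- numeric(0)
  for (n3 in 0:n) for (n2 in 0:(n - n3)) {
    n1 <- n - n3 - n2
    v <- rep(c(3, 2, 1), times = c(n3, n2, n1))
    if (abs(round(base::mean(v), digits) - round(mean, digits)) > 1e-9) next
    cand[[length(cand) + 1L]] <- v
    sds <- c(sds, if (n > 1) stats::sd(v) else 0)
  }
  if (!length(cand)) {
    return(structure(list(candidates = list(), sd = numeric(0),
                          sd_diff = numeric(0), tie = FALSE,
                          mean = mean, printed_sd = sd, n = n),
                     class = "score_reconstruction"))
  }
  d <- abs(sds - sd)
  o <- order(d)
  tie <- length(d) > 1 && abs(sort(d)[1] - sort(d)[2]) < 1e-12
  structure(list(candidates = cand[o], sd = sds[o], sd_diff = d[o],
                 tie = tie, mean = mean, printed_sd = sd, n = n),
            class = "score_reconstruction")
}

#' @export
print.score_reconstruction <- function(x, ...) {
  cat(sprintf("score reconstruction for mean %.3g, SD %.3g, n = %d:\n",
              x$mean, x$printed_sd, x$n))
  if (!length(x$candidates)) {
    cat("  no admissible score vector\n")
    return(invisible(x))
  }
  for (i in seq_along(x$candidates))
    cat(sprintf("  {%s}  SD %.3f (|diff| %.3f)\n",
                paste(x$candidates[[i]], collapse = ","),
                x$sd[i], x$sd_diff[i]))
  if (x$tie) cat("  note: best SD distance is tied\n")
  invisible(x)
}

#' Best admissible score vector
#'
#' Convenience accessor for [reconstruct_stage_scores()]: the top-ranked
#' vector. Errors when no vector is admissible; warns on a tie.
#'
#' @inheritParams reconstruct_stage_scores
#' @return Numeric score vector of length `n`.
#' @export
best_stage_scores <- function(mean, sd, n, digits = 1) {
  rec <- reconstruct_stage_scores(mean, sd, n, digits)
  if (!length(rec$candidates))
    stop("no score vector is consistent with the printed summary")
  if (rec$tie)
    warning("best SD distance is tied; returning the first candidate")
  rec$candidates[[1]]
}
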