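#' Cross-method fixation split / not-classified comparison
#'
#' For every fixation F of table `a`, counts the fixations of table `b` whose
#' time span lies within F's span (with a containment tolerance of one sample
#' period, so one-sample onset/offset jitter cannot mask a true split). Two or
#' more contained fixations mean the other method split F; no contained
#' fixation and no overlapping `b` fixation at all means F was not classified
#' by the other method. Call with the tables swapped for the other direction.
#'
#' @param a,b event tables from [parse_recording()] over the same recording
#'   and trials.
#' @param tolerance_ms containment tolerance (default: one sample period —
#'   pass `1000 / sampling_rate`).
#' @return A data frame with one row per fixation of `a`: `Trial, Start, End,
#'   contained` (count of `b` fixations inside), `split` (contained >= 2) and
#'   `unmatched` (no overlapping `b` fixation).
#' @export
compare_parsings <- function(a, b, tolerance_ms = 2) {
  fa <- a[a$Value == "f", , drop = FALSE]
  fb <- b[b$Value == "f", , drop = FALSE]
  ta <- sort(unique(a$Trial)); tb <- sort(unique(b$Trial))
  if (!identical(ta, tb))
    stop("the two event tables cover different trial sets")
  if (!nrow(fa))
    return(data.frame(Trial = integer(), Start = numeric(), End = numeric(),
                      contained = integer(), split = logical(),
                      unmatched = logical()))
  res <- lapply(seq_len(nrow(fa)), function(k) {
    bt <- fb[fb$Trial == fa$Trial[k], , drop = FALSE]
    contained <- sum(bt$Start >= fa$Start[k] - tolerance_ms &
                       bt$End <= fa$End[k] + tolerance_ms)
    overlapping <- sum(bt$Start < fa$End[k] & bt$End > fa$Start[k])
    data.frame(Trial = fa$Trial[k], Start = fa$Start[k], End = fa$End[k],
               contained = contained, split = contained >= 2,
               unmatched = overlapping == 0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise a two-way parsing comparison
#'
#' The reporting quadruple for each direction: total fixations, how many were
#' split by the other method, how many extra fixations those splits created
#' (sum of contained-minus-one over split fixations), and how many were not
#' classified by the other method at all.
#'
#' @inheritParams compare_parsings
#' @param names_ab labels for the two methods.
#' @return Data frame with one row per direction: `method, n_fixations,
#'   n_split, n_extra, n_unmatched`.
#' @export
compare_summary <- function(a, b, tolerance_ms = 2,
                            names_ab = c("a", "b")) {
  quad <- function(x, y) {
    cmp <- compare_parsings(x, y, tolerance_ms)
    data.frame(n_fixations = nrow(cmp), n_split = sum(cmp$split),
               n_extra = sum(pmax(cmp$contained[cmp$split] - 1, 0)),
               n_unmatched = sum(cmp$unmatched))
  }
  out <- rbind(cbind(data.frame(method = names_ab[1]), quad(a, b)),
               cbind(data.frame(method = names_ab[2]), quad(b, a)))
  rownames(out) <- NULL
  out
}
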