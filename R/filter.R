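#' High-confidence CNV filter parameters
#'
#' The four standard read-depth filters for CNVnator-style calls, applied
#' with strict inequalities: e-value below `maxEValue`, deletion read depth
#' below `delRdMax`, duplication read depth above `dupRdMin`, and call length
#' strictly greater than `minLengthBp`. Boundary values (e.g. a deletion with
#' RD exactly 0.7, or a call of exactly 1000 bp) are rejected.
#'
#' @param maxEValue Significance cutoff; keep calls with `e_value < maxEValue`.
#' @param delRdMax Keep deletions with `rd < delRdMax`.
#' @param dupRdMin Keep duplications with `rd > dupRdMin`.
#' @param minLengthBp Keep calls with width `> minLengthBp`.
#' @return A `cnvFilterParams` list.
#' @export
cnvFilterParams <- function(maxEValue = 0.01, delRdMax = 0.7,
                            dupRdMin = 1.3, minLengthBp = 1000L) {
  stopifnot(maxEValue > 0, maxEValue <= 1,
            delRdMax > 0, dupRdMin > delRdMax, minLengthBp >= 0)
  structure(list(maxEValue = maxEValue, delRdMax = delRdMax,
                 dupRdMin = dupRdMin, minLengthBp = as.integer(minLengthBp)),
            class = "cnvFilterParams")
}

#' Filter CNV calls to the high-confidence set
#'
#' A call is kept iff it passes all four rules of [cnvFilterParams()]. The
#' report counts rejections per rule; a call failing several rules increments
#' each corresponding counter, so rule counts can sum to more than the number
#' of rejected calls.
#'
#' @param calls A `GRanges` of calls (see [cnvCalls()]).
#' @param params A [cnvFilterParams()] object.
#' @return A list with elements `kept` (the filtered `GRanges`) and `report`
#'   (a one-row `data.frame` with columns `n_total`, `n_kept`, `fail_e_value`,
#'   `fail_rd`, `fail_length`).
#' @export
filterCalls <- function(calls, params = cnvFilterParams()) {
  stopifnot(inherits(params, "cnvFilterParams"))
  ok_e <- calls$e_value < params$maxEValue
  ok_rd <- ifelse(calls$cnv_type == "DEL",
                  calls$rd < params$delRdMax,
                  calls$rd > params$dupRdMin)
  ok_len <- GenomicRanges::width(calls) > params$minLengthBp
  keep <- ok_e & ok_rd & ok_len
  list(kept = calls[keep],
       report = data.frame(n_total = length(calls),
                           n_kept = sum(keep),
                           fail_e_value = sum(!ok_e),
                           fail_rd = sum(!ok_rd),
                           fail_length = sum(!ok_len)))
}
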