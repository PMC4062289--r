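# Comparison of a domain term list against the same pipeline's output on a
# general-language reference corpus. This stage annotates and reports; it
# does not filter, because in near-exclusively domain text the overlap with
# general language is small and mostly itself domain-related.

#' Annotate domain terms with their reference-corpus status
#'
#' Both lists must use the same normalisation (simplified base forms, same
#' score variant). Every domain term is labelled `absent`, `present` or
#' `present_higher_ref` (present with a strictly higher reference score),
#' and the common-term set is summarised split by single-word vs multi-word
#' forms.
#'
#' @param domain data.frame with columns `form` and the score column.
#' @param reference data.frame with columns `form` and the score column
#'   (the ranking export of the reference corpus run).
#' @param score name of the score column present in both inputs
#'   (default `"c1_value"`).
#' @return list of class `clt_refcomp` with `terms` (the annotated domain
#'   data.frame, new columns `ref_score` and `ref_status`) and `summary`
#'   (counts: common, common 1-word / multi-word, higher-in-reference and
#'   its split).
#' @export
compare_to_reference <- function(domain, reference, score = "c1_value") {
  for (nm in list(c("domain", score), c("reference", score))) {
    obj <- if (nm[[1]] == "domain") domain else reference
    if (!all(c("form", nm[[2]]) %in% names(obj))) {
      stop(sprintf("%s input needs columns 'form' and '%s'", nm[[1]], nm[[2]]),
           call. = FALSE)
    }
  }
  ref_score <- reference[[score]][match(domain$form, reference$form)]
  status <- ifelse(is.na(ref_score), "absent",
            ifelse(ref_score > domain[[score]], "present_higher_ref",
                   "present"))
  out <- domain
  out$ref_score <- ref_score
  out$ref_status <- status
  n_words <- lengths(strsplit(out$form, " ", fixed = TRUE))
  common <- status != "absent"
  higher <- status == "present_higher_ref"
  summary <- data.frame(
    group = c("common", "common_1word", "common_multiword",
              "higher_in_reference", "higher_1word", "higher_multiword"),
    n = c(sum(common), sum(common & n_words == 1L), sum(common & n_words > 1L),
          sum(higher), sum(higher & n_words == 1L), sum(higher & n_words > 1L)),
    stringsAsFactors = FALSE
  )
  structure(list(terms = out, summary = summary), class = "clt_refcomp")
}

#' @export
print.clt_refcomp <- function(x, ...) {
  cat("<clt_refcomp>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
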