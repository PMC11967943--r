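#' The seven canonical EPG waveform labels
#'
#' EPG recordings of aphid feeding are annotated with seven behavioural
#' waveforms: `NP` (non-probing, stylet outside the plant), `C` (pathway
#' phase in epidermis/mesophyll), `pd` (potential drop, a brief intracellular
#' puncture occurring only during C), `E1` (phloem salivation), `E2` (phloem
#' ingestion), `F` (derailed stylet) and `G` (xylem ingestion).
#'
#' The canonical order `NP < C < pd < E1 < E2 < F < G` is used everywhere in
#' the package: factor levels, classifier output columns, confusion-matrix
#' axes, and deterministic tie-breaking.
#'
#' @format A character vector of length 7.
#' @export
EPG_LABELS <- c("NP", "C", "pd", "E1", "E2", "F", "G")

#' Default numeric waveform codes
#'
#' Legacy annotation files often store waveforms as small integers rather
#' than mnemonic codes. The exact integer convention varies between
#' laboratories, so the mapping is configurable; this default assigns
#' `1 = NP`, `2 = C`, `3 = E1`, `4 = E2`, `5 = F`, `6 = G`, `7 = pd`.
#' It is a documented package convention, not a fixed standard.
#'
#' @format A named integer vector (names are waveform codes).
#' @export
EPG_NUMERIC_ALIASES <- c(NP = 1L, C = 2L, E1 = 3L, E2 = 4L, F = 5L, G = 6L, pd = 7L)

#' Coerce waveform label tokens to a canonical factor
#'
#' Accepts mnemonic codes (case-sensitive, e.g. `"pd"`), or integer codes
#' interpreted through `aliases`. Unknown tokens raise an error naming the
#' offending token.
#'
#' @param x character or integer vector of label tokens.
#' @param aliases named integer vector mapping waveform codes to integers
#'   (default [EPG_NUMERIC_ALIASES]).
#' @return factor with levels [EPG_LABELS].
#' @export
as_epg_label <- function(x, aliases = EPG_NUMERIC_ALIASES) {
  if (is.factor(x)) x <- as.character(x)
  x <- trimws(as.character(x))
  numeric_tokens <- grepl("^[0-9]+$", x)
  if (any(numeric_tokens)) {
    rev_map <- stats::setNames(names(aliases), as.character(aliases))
    mapped <- rev_map[x[numeric_tokens]]
    if (anyNA(mapped)) {
      bad <- x[numeric_tokens][is.na(mapped)][1L]
      stop("unknown numeric waveform code: '", bad, "'", call. = FALSE)
    }
    x[numeric_tokens] <- mapped
  }
  bad <- setdiff(unique(x), EPG_LABELS)
  if (length(bad) > 0) {
    stop("unknown waveform label: '", bad[1L], "'", call. = FALSE)
  }
  factor(x, levels = EPG_LABELS)
}
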