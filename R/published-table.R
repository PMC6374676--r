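#' Reference results of a 36-year Alpine breeding-bird study
#'
#' Loads the packaged transcription of the per-landmark results of a
#' long-term (1982--2017) point-count monitoring study of breeding birds in
#' the Lombardy Alps: 125 reliable reference points across 29 species, with
#' the effort-weighted year trend (`beta_y`, `p_y`), the printed pattern of
#' elevational range change, the two-driver weighted regression
#' (`beta_tn`, `p_tn`, `beta_sf`, `p_sf`, `r_adj`), the four contributed
#' deviance fractions, and the printed range-change driver. This table is
#' the download-free surface on which the package's classification rules are
#' validated.
#'
#' Printed p-values below resolution (`"<0.001"`) are stored as 0.0005; a
#' printed `"0.000"` is stored as 0. The `extremes` column carries the
#' study's reported outcome of the extreme-slope comparison
#' (`"obl_steeper"`) for the two species whose extreme landmarks both moved
#' significantly, since the table prints no standard errors. The `dw` column
#' flags rows with significant temporal autocorrelation at the
#' Durbin--Watson test (diagnostic only).
#'
#' @return Data frame with 125 rows and columns `species`, `habitat`,
#'   `migration`, `landmark`, `beta_y`, `p_y`, `dw`, `pattern`, `beta_tn`,
#'   `p_tn`, `beta_sf`, `p_sf`, `r_adj`, `partial_tn`, `shared`,
#'   `partial_sf`, `unexplained`, `driver`, `extremes`.
#' @export
alpine_range_shifts <- function() {
  path <- system.file("extdata", "alpine_range_shifts.csv",
                      package = "upslope", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("species", "habitat", "migration", "landmark", "beta_y", "p_y",
            "dw", "pattern", "beta_tn", "p_tn", "beta_sf", "p_sf", "r_adj",
            "partial_tn", "shared", "partial_sf", "unexplained", "driver",
            "extremes")
  if (!identical(names(raw), need))
    stop("malformed reference table: unexpected columns")
  parse_p <- function(x) {
    x <- trimws(x)
    out <- rep(NA_real_, length(x))
    lt <- grepl("^<", x)
    out[lt] <- as.numeric(sub("^<", "", x[lt])) / 2
    out[!lt & nzchar(x)] <- as.numeric(x[!lt & nzchar(x)])
    out
  }
  num <- function(x) ifelse(nzchar(trimws(x)), as.numeric(x), NA_real_)
  df <- data.frame(
    species = raw$species, habitat = raw$habitat, migration = raw$migration,
    landmark = raw$landmark,
    beta_y = num(raw$beta_y), p_y = parse_p(raw$p_y),
    dw = raw$dw == "1", pattern = raw$pattern,
    beta_tn = num(raw$beta_tn), p_tn = parse_p(raw$p_tn),
    beta_sf = num(raw$beta_sf), p_sf = parse_p(raw$p_sf),
    r_adj = num(raw$r_adj),
    partial_tn = num(raw$partial_tn), shared = num(raw$shared),
    partial_sf = num(raw$partial_sf), unexplained = num(raw$unexplained),
    driver = raw$driver,
    extremes = ifelse(nzchar(raw$extremes), raw$extremes, NA_character_),
    stringsAsFactors = FALSE)
  if (nrow(df) != 125) stop("malformed reference table: expected 125 rows")
  df
}

#' Re-derive species pattern calls from the reference table
#'
#' Applies [classify_pattern()] to the transcribed per-landmark trend
#' columns of every species, using the table's reported extreme-slope
#' comparison where both extremes are significant.
#'
#' @param tab table from [alpine_range_shifts()].
#' @param alpha significance level.
#' @return Data frame `species`, `pattern` (derived), `pattern_printed`.
#' @export
published_pattern_calls <- function(tab = alpine_range_shifts(),
                                    alpha = 0.05) {
  sp <- unique(tab$species)
  rows <- lapply(sp, function(s) {
    d <- tab[tab$species == s, ]
    cmp <- unique(d$extremes[!is.na(d$extremes)])
    call <- classify_pattern(
      data.frame(landmark = d$landmark, slope = d$beta_y, p = d$p_y),
      alpha = alpha,
      extremes_comparison = if (length(cmp)) cmp else NULL)
    data.frame(species = s, pattern = call$pattern,
               pattern_printed = d$pattern[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Re-derive driver calls from the reference table
#'
#' For every significant reference point (positive trend with `p_y` at most
#' `alpha`), runs [classify_driver()] on the four transcribed deviance
#' fractions and [finalize_driver_call()] on the transcribed coefficients
#' and landmark kind.
#'
#' @inheritParams published_pattern_calls
#' @return Data frame with one row per significant reference point:
#'   `species`, `habitat`, `migration`, `landmark`, `pattern`, `raw`,
#'   `final`, `dde`, `label` (derived) and `driver_printed`.
#' @export
published_driver_calls <- function(tab = alpine_range_shifts(),
                                   alpha = 0.05) {
  sig <- !is.na(tab$p_y) & tab$p_y <= alpha & tab$beta_y > 0
  d <- tab[sig, ]
  rows <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    part <- list(partial_tn = r$partial_tn, shared = r$shared,
                 partial_sf = r$partial_sf, unexplained = r$unexplained)
    raw <- classify_driver(part)
    reg <- list(beta_sf = r$beta_sf, p_tn = r$p_tn, p_sf = r$p_sf)
    call <- finalize_driver_call(raw, reg, part, r$landmark, alpha)
    data.frame(species = r$species, habitat = r$habitat,
               migration = r$migration, landmark = r$landmark,
               pattern = r$pattern, raw = call$raw, final = call$final,
               dde = call$dde, label = call$label,
               driver_printed = r$driver, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
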