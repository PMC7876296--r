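#' Canonical autonomic nervous system (ANS) proxy set
#'
#' The pipeline works on 16 short-term variability proxies derived from the
#' RR-interval tachogram and the systolic arterial pressure (SAP) series:
#' heart rate, mean RR, total and band-limited spectral powers, normalized
#' low/high-frequency powers, central frequencies, the stand-minus-rest shift
#' in normalized LF power, the baroreflex alpha index, and brachial/mean
#' arterial pressures.  Internally the columns carry syntactic ASCII names;
#' on CSV input/output they are mapped to the display names used in the
#' field (including the Greek-letter forms).
#'
#' @return `proxy_names()` returns the 16 internal column names, in canonical
#'   order.  `proxy_display_names()` returns the matching display (CSV
#'   header) names.
#' @examples
#' proxy_names()
#' @export
proxy_names <- function() {
  c("HR", "RR_Mean", "RR_TP", "RR_LFa", "RR_HFa", "RR_LFnu", "RR_HFnu",
    "RR_LFHF", "RR_LFHz", "RR_HFHz", "dRR_LFnu", "alpha_index",
    "SAP", "DAP", "SAP_Mean", "SAP_LFa")
}

#' @rdname proxy_names
#' @export
proxy_display_names <- function() {
  c("HR", "RR Mean", "RR TP", "RR LFa", "RR HFa", "RR LFnu", "RR HFnu",
    "RR LF/HF", "RR LFHz", "RR HFHz", "\u0394RR LFnu", "\u03b1 index",
    "SAP", "DAP", "SAP Mean", "SAP LFa")
}

# Link scale used by the synthetic generator to keep each proxy in its legal
# range: "log" (strictly positive), "logit" (bounded interval, see
# proxy_bounds), "identity" (unbounded).
proxy_links <- function() {
  c(HR = "log", RR_Mean = "log", RR_TP = "log", RR_LFa = "log",
    RR_HFa = "log", RR_LFnu = "logit", RR_HFnu = "logit", RR_LFHF = "log",
    RR_LFHz = "logit", RR_HFHz = "logit", dRR_LFnu = "identity",
    alpha_index = "log", SAP = "log", DAP = "log", SAP_Mean = "log",
    SAP_LFa = "log")
}

# (lower, upper) bounds for the logit-linked proxies; normalized units live
# in (0, 100), central frequencies in the standard LF and HF analysis bands.
proxy_bounds <- function() {
  list(RR_LFnu = c(0, 100), RR_HFnu = c(0, 100),
       RR_LFHz = c(0.03, 0.14), RR_HFHz = c(0.14, 0.45))
}

# Skewed power-like proxies log-transformed before age/gender adjustment.
default_log_vars <- function() c("RR_TP", "RR_LFa", "RR_HFa", "SAP_LFa")

# map a latent (link-scale) matrix to observed proxies, column by column
squash_links <- function(z) {
  links <- proxy_links()
  bounds <- proxy_bounds()
  out <- z
  for (j in colnames(z)) {
    out[, j] <- switch(links[[j]],
      log = exp(z[, j]),
      logit = {
        b <- bounds[[j]]
        b[1] + (b[2] - b[1]) * stats::plogis(z[, j])
      },
      identity = z[, j])
  }
  out
}
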