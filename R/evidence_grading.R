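#' Grade the strength of evidence of a 9-test battery
#'
#' Classifies the significance pattern of the battery into six ordered
#' levels, applying the rules in strict precedence from strongest to
#' weakest (the first matching rule wins):
#'
#' * `strong` - all nine tests significant;
#' * `almost_strong` - exactly one test not significant;
#' * `medium_strong` - KW significant, at least one median and one density
#'   test significant, and both JT and HN significant;
#' * `medium` - at least one of the KW/median/density tests significant and
#'   at least one of JT/HN significant;
#' * `weak` - at least one test significant;
#' * `insignificant` - no test significant.
#'
#' Every one of the 512 possible significance patterns receives exactly one
#' level, and flipping any single test to significant never lowers the
#' level (each rule is monotone in the pattern and precedence takes the
#' strongest).
#'
#' @param battery a `carproc_battery` from [run_battery()], or a logical
#'   vector of 9 significance flags in battery order (KW, 3 median, 3
#'   density, JT, HN).
#' @return A list of class `carproc_grade`: `level`, `concordant` (0-9),
#'   and per-family counts `kw`, `median`, `ba`, `jt`, `hn`.
#' @examples
#' grade_evidence(rep(TRUE, 9))$level
#' grade_evidence(c(TRUE, rep(FALSE, 8)))$level
#' @export
grade_evidence <- function(battery) {
  if (inherits(battery, "carproc_battery"))
    sig <- vapply(battery$tests, `[[`, logical(1), "significant")
  else sig <- as.logical(battery)
  if (length(sig) != 9 || anyNA(sig))
    stop("battery must supply exactly 9 significance outcomes")
  kw <- sig[1]; med <- sum(sig[2:4]); ba <- sum(sig[5:7])
  jt <- sig[8]; hn <- sig[9]
  s <- sum(sig)
  level <- if (s == 9) "strong"
  else if (s == 8) "almost_strong"
  else if (kw && med >= 1 && ba >= 1 && jt && hn) "medium_strong"
  else if ((kw || med >= 1 || ba >= 1) && (jt || hn)) "medium"
  else if (s >= 1) "weak"
  else "insignificant"
  structure(list(level = level, concordant = s, kw = as.integer(kw),
                 median = med, ba = ba, jt = as.integer(jt),
                 hn = as.integer(hn)),
            class = "carproc_grade")
}

#' Ordered evidence levels
#'
#' @return Character vector of the six levels from weakest to strongest.
#' @export
evidence_levels <- function() {
  c("insignificant", "weak", "medium", "medium_strong", "almost_strong",
    "strong")
}

#' Synoptic summary of batteries across indicators
#'
#' One row per indicator: the nine cell outcomes (`=` / `!=` for
#' non-directional tests, trend arrows for JT/HN), the concordant count and
#' the evidence grade, mirroring the usual synoptic display.
#'
#' @param batteries named list of `carproc_battery` objects (one per
#'   indicator).
#' @return data.frame with columns `indicator`, `KW`, `Mt_NW_OW`,
#'   `Mt_NW_OB`, `Mt_OW_OB`, `BA_NW_OW`, `BA_NW_OB`, `BA_OW_OB`, `JT`,
#'   `HN`, `concordant`, `grade`.
#' @export
synoptic_table <- function(batteries) {
  if (length(batteries) == 0) stop("at least one battery is required")
  rows <- lapply(names(batteries), function(ind) {
    b <- batteries[[ind]]
    sig <- vapply(b$tests, `[[`, logical(1), "significant")
    arrow <- if (b$direction == "increasing") "\u2197" else "\u2198"
    cells <- c(ifelse(sig[1:7], "\u2260", "="),
               ifelse(sig[8:9], arrow, "="))
    g <- grade_evidence(b)
    data.frame(indicator = ind, KW = cells[1], Mt_NW_OW = cells[2],
               Mt_NW_OB = cells[3], Mt_OW_OB = cells[4],
               BA_NW_OW = cells[5], BA_NW_OB = cells[6],
               BA_OW_OB = cells[7], JT = cells[8], HN = cells[9],
               concordant = g$concordant, grade = g$level,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
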