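#' Cumulative noise exposure (CNE)
#'
#' Combines the 8-hour equivalent A-weighted sound pressure level with
#' years of noise exposure on the equal-energy principle:
#' `CNE = SPL + 10 * log10(years)`, in dB(A)-years.  One extra year at a
#' fixed level adds energy, ten-fold exposure time adds 10 dB(A)-years,
#' and a single year of exposure gives CNE equal to the SPL itself.
#'
#' @param spl sound pressure level in dB(A) (`L_Aeq,8h`); must be > 0.
#' @param years_exposure years of occupational noise exposure; must be > 0.
#' @return CNE in dB(A)-years, vectorized over both arguments.
#' @examples
#' computeCNE(85, 1)   # 85
#' computeCNE(85, 10)  # 95
#' @export
computeCNE <- function(spl, years_exposure) {
  if (any(!is.na(spl) & spl <= 0))
    stop("'spl' must be > 0 dB(A)")
  if (any(!is.na(years_exposure) & years_exposure <= 0))
    stop("'years_exposure' must be > 0")
  spl + 10 * log10(years_exposure)
}

AUDIO_FREQS <- c("500", "1000", "2000", "3000", "4000", "6000")

checkThresholds <- function(thr, ear, need) {
  if (is.null(names(thr)))
    stop("thresholds must be named by frequency (Hz)")
  missing <- setdiff(need, names(thr))
  if (length(missing))
    stop(sprintf("missing %s-ear threshold at %s Hz",
                 ear, paste(missing, collapse = ", ")))
  v <- as.numeric(thr[need])
  if (any(!is.finite(v)) || any(v < -10) || any(v > 120))
    stop(sprintf("%s-ear thresholds must be finite and within [-10, 120] dB HL",
                 ear))
  v
}

#' Binaural high-frequency threshold average (BHFTA)
#'
#' Mean of the 3000, 4000 and 6000 Hz air-conduction thresholds over both
#' ears (six values), in dB HL.  BHFTA >= 40 dB is one of the two
#' audiometric criteria for occupational noise-induced hearing loss.
#'
#' @param left,right named numeric vectors of per-frequency thresholds in
#'   dB HL; names are frequencies in Hz and must include 3000, 4000, 6000.
#' @return BHFTA in dB.
#' @examples
#' computeBHFTA(c(`3000` = 30, `4000` = 40, `6000` = 50),
#'              c(`3000` = 40, `4000` = 50, `6000` = 60))  # 45
#' @export
computeBHFTA <- function(left, right) {
  hf <- c("3000", "4000", "6000")
  mean(c(checkThresholds(left, "left", hf),
         checkThresholds(right, "right", hf)))
}

#' Monaural weighted threshold value (MTWV)
#'
#' Weighted single-ear threshold: 90% of the mean speech-frequency
#' threshold (500/1000/2000 Hz) plus 10% of the 4000 Hz threshold.
#' MTWV >= 26 dB (in at least one ear) is the second audiometric
#' criterion for noise-induced hearing loss.
#'
#' @param thresholds named numeric vector of one ear's thresholds in dB
#'   HL; names are frequencies in Hz and must include 500, 1000, 2000, 4000.
#' @param ear label used in error messages (`"left"`/`"right"`).
#' @return MTWV in dB.
#' @examples
#' computeMTWV(c(`500` = 20, `1000` = 20, `2000` = 20, `4000` = 60))  # 24
#' @export
computeMTWV <- function(thresholds, ear = "this") {
  v <- checkThresholds(thresholds, ear, c("500", "1000", "2000", "4000"))
  0.9 * mean(v[1:3]) + 0.1 * v[4]
}

#' Classify hearing status from an audiogram
#'
#' Applies the occupational NIHL case definition: a subject is a `case`
#' when BHFTA >= 40 dB and the worse-ear MTWV >= 26 dB, a `control` when
#' BHFTA < 40 dB and the worse-ear MTWV < 26 dB, and `indeterminate`
#' otherwise (discordant criteria).  The worse (larger) ear is used for
#' the monaural criterion; set `ear = "better"` for the lenient reading.
#'
#' @param left,right named numeric vectors of per-frequency thresholds
#'   (dB HL) covering 500--6000 Hz as required by [computeBHFTA()] and
#'   [computeMTWV()].
#' @param bhfta_cut,mtwv_cut diagnostic cutoffs in dB.
#' @param ear which ear's MTWV the monaural criterion uses.
#' @return `"case"`, `"control"` or `"indeterminate"`.
#' @export
classifyHearingStatus <- function(left, right, bhfta_cut = 40, mtwv_cut = 26,
                                  ear = c("worse", "better")) {
  ear <- match.arg(ear)
  bhfta <- computeBHFTA(left, right)
  mtwvs <- c(computeMTWV(left, "left"), computeMTWV(right, "right"))
  mtwv <- if (ear == "worse") max(mtwvs) else min(mtwvs)
  if (bhfta >= bhfta_cut && mtwv >= mtwv_cut) return("case")
  if (bhfta < bhfta_cut && mtwv < mtwv_cut) return("control")
  "indeterminate"
}

# column names used for per-ear thresholds in cohort colData
audioColumns <- function() {
  as.vector(outer(c("thr_left_", "thr_right_"), AUDIO_FREQS, paste0))
}

#' Derive audiometric summaries and hearing status for a whole cohort
#'
#' Expects per-ear threshold columns `thr_left_<freq>` / `thr_right_<freq>`
#' (freq in 500, 1000, 2000, 3000, 4000, 6000) in `colData` and adds
#' `bhfta`, `mtwv_left`, `mtwv_right` and (when `overwrite_status`) a
#' derived `status`.
#'
#' @param cohort a [SnpCohort-class] with audiometric columns.
#' @param overwrite_status replace the stored status with the audiometric
#'   classification (default `FALSE`).
#' @return The cohort with derived columns added.
#' @export
deriveHearingStatus <- function(cohort, overwrite_status = FALSE) {
  cd <- as.data.frame(colData(cohort))
  cols <- audioColumns()
  if (!all(cols %in% colnames(cd)))
    stop("cohort lacks audiometric threshold columns: ",
         paste(setdiff(cols, colnames(cd)), collapse = ", "))
  res <- t(vapply(seq_len(ncol(cohort)), function(i) {
    left <- setNames(unlist(cd[i, paste0("thr_left_", AUDIO_FREQS)]),
                     AUDIO_FREQS)
    right <- setNames(unlist(cd[i, paste0("thr_right_", AUDIO_FREQS)]),
                      AUDIO_FREQS)
    c(bhfta = computeBHFTA(left, right),
      mtwv_left = computeMTWV(left, "left"),
      mtwv_right = computeMTWV(right, "right"))
  }, numeric(3)))
  colData(cohort)$bhfta <- res[, "bhfta"]
  colData(cohort)$mtwv_left <- res[, "mtwv_left"]
  colData(cohort)$mtwv_right <- res[, "mtwv_right"]
  if (overwrite_status) {
    mtwv <- pmax(res[, "mtwv_left"], res[, "mtwv_right"])
    colData(cohort)$status <- ifelse(
      res[, "bhfta"] >= 40 & mtwv >= 26, "case",
      ifelse(res[, "bhfta"] < 40 & mtwv < 26, "control", "indeterminate"))
  }
  validObject(cohort)
  cohort
}
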