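#' Published cohort summary values used as reference inputs
#'
#' Summary statistics of the original 19 + 19 subject study (group means of
#' the volumetric measures, the reported map-regression fits, and the
#' protocol constants). These are inputs for comparisons and for
#' sanity-checking pipeline output scales; they are not recomputed by the
#' package.
#'
#' @return A list:
#' \describe{
#'   \item{icv_ml}{named vector, group-mean intracranial volume (mL):
#'     reference 1400, patient 1357.}
#'   \item{bpf_pct}{group-mean brain parenchymal fraction (%): 89.9 / 82.1.}
#'   \item{vf_pct}{group-mean ventricular fraction (%): 1.0 / 2.5.}
#'   \item{wm}{Table of whole-WM (R1, R2, PD) group means: reference
#'     (1.20, 11.1, 74), patient (1.07, 10.2, 77).}
#'   \item{wm_cropped}{the same for 2 mm cropped ROIs: (1.35, 11.7, 71) and
#'     (1.22, 10.8, 74).}
#'   \item{map_regression}{reported slope and R^2 of the slope-on-T
#'     regression per parameter.}
#'   \item{n_subjects}{19 per group.}
#'   \item{edss}{mean 3.7, range 1-8.5.}
#' }
#' @export
study_reference_values <- function() {
  list(
    icv_ml = c(reference = 1400, patient = 1357),
    bpf_pct = c(reference = 89.9, patient = 82.1),
    vf_pct = c(reference = 1.0, patient = 2.5),
    wm = rbind(reference = c(R1 = 1.20, R2 = 11.1, PD = 74),
               patient = c(R1 = 1.07, R2 = 10.2, PD = 77)),
    wm_cropped = rbind(reference = c(R1 = 1.35, R2 = 11.7, PD = 71),
                       patient = c(R1 = 1.22, R2 = 10.8, PD = 74)),
    map_regression = rbind(R1 = c(slope = 0.53, r_squared = 0.50),
                           R2 = c(slope = 0.49, r_squared = 0.48),
                           PD = c(slope = 0.50, r_squared = 0.46)),
    n_subjects = c(reference = 19, patient = 19),
    edss = list(mean = 3.7, range = c(1, 8.5))
  )
}
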