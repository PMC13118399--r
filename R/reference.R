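#' Size classes used throughout the package
#'
#' The wet-sieving scheme separates soil into four size classes:
#' large macroaggregates (>2 mm), small macroaggregates (0.25-2 mm),
#' microaggregates (0.053-0.25 mm) and the silt-and-clay fraction
#' (<0.053 mm). The first two classes together are the ">0.25 mm
#' macroaggregates" that define the R0.25 metrics.
#'
#' @return Character vector of the four class labels, in decreasing size order.
#' @export
size_class_labels <- function() {
  c(">2 mm", "0.25-2 mm", "0.053-0.25 mm", "<0.053 mm")
}

# column-safe internal codes for the four classes
class_codes <- function() c("gt2", "m025_2", "m0053_025", "lt0053")

#' Reference aggregate data from the motivating field trial
#'
#' Treatment-level means and standard deviations (n = 3 field replicates)
#' of the wet-sieved aggregate measurements from a five-year maize-legume
#' intercropping experiment with seven cropping systems: maize monoculture
#' (MM) and maize intercropped with red clover (MI1), sesbania (MI2),
#' soybean (MI3), hairy vetch (MI4), common vetch (MI5) and yellow sweet
#' clover (MI6). These values serve three purposes: worked examples for
#' the aggregate metrics, default targets for the synthetic-data
#' generator, and inputs for the desk-scale identity checks.
#'
#' @return A list with components:
#' \describe{
#'   \item{treatments}{character vector of the seven treatment codes}
#'   \item{mass_mean, mass_sd}{7 x 4 matrices of aggregate mass
#'     proportions (\%) per size class}
#'   \item{r025_mass_mean, r025_mass_sd}{printed R0.25-mass column (\%)}
#'   \item{soc_mean, soc_sd}{7 x 4 matrices of SOC concentration
#'     (g C per kg aggregate fraction)}
#'   \item{cdist_mean, cdist_sd}{7 x 4 matrices of aggregate-associated
#'     C distribution (\%)}
#'   \item{r025_soc_mean, r025_soc_sd}{printed R0.25-SOC column (\%)}
#'   \item{total_soc_mean, total_soc_sd}{bulk soil SOC (g kg^-1)}
#'   \item{groups}{the two treatment groups the trial separated into:
#'     Group1 = MI1, MI2 (taproot legumes) and Group2 = MI3-MI6
#'     (fibrous-root legumes)}
#' }
#' @export
study_reference <- function() {
  tr <- c("MM", "MI1", "MI2", "MI3", "MI4", "MI5", "MI6")
  cls <- class_codes()
  m <- function(x) matrix(x, nrow = 7, ncol = 4, byrow = TRUE,
                          dimnames = list(tr, cls))
  list(
    treatments = tr,
    mass_mean = m(c(10.16, 22.01, 55.06, 12.77,
                    7.43, 29.57, 27.71, 35.29,
                    10.16, 28.38, 33.82, 27.64,
                    16.05, 34.20, 37.73, 12.02,
                    19.74, 36.85, 27.96, 15.45,
                    16.72, 38.67, 31.64, 12.98,
                    16.12, 42.14, 30.20, 11.55)),
    mass_sd = m(c(3.00, 1.42, 3.95, 1.93,
                  2.87, 3.50, 3.54, 6.51,
                  1.64, 1.19, 4.46, 2.28,
                  4.80, 4.00, 3.58, 1.48,
                  3.97, 3.55, 1.29, 0.92,
                  3.51, 3.81, 4.48, 2.63,
                  1.52, 5.42, 4.05, 2.24)),
    r025_mass_mean = stats::setNames(
      c(32.17, 37.00, 38.54, 50.25, 56.59, 55.38, 58.25), tr),
    r025_mass_sd = stats::setNames(
      c(4.16, 5.52, 2.37, 4.19, 0.51, 7.10, 5.88), tr),
    soc_mean = m(c(19.63, 21.39, 16.37, 12.97,
                   26.22, 28.40, 23.28, 15.88,
                   30.97, 26.63, 23.31, 17.51,
                   24.81, 24.14, 23.70, 15.52,
                   24.65, 25.07, 20.97, 15.90,
                   24.36, 24.84, 21.45, 16.02,
                   26.39, 25.44, 22.67, 14.49)),
    soc_sd = m(c(0.68, 0.34, 1.25, 1.48,
                 2.52, 0.81, 0.45, 2.22,
                 2.33, 1.60, 0.42, 1.98,
                 2.66, 0.22, 1.74, 0.64,
                 0.06, 0.51, 0.74, 0.24,
                 0.10, 0.97, 0.31, 0.12,
                 2.81, 1.22, 1.11, 0.94)),
    cdist_mean = m(c(11.44, 27.12, 51.88, 9.56,
                     8.75, 37.38, 28.66, 25.22,
                     13.05, 32.49, 33.77, 20.69,
                     16.86, 35.99, 39.04, 8.10,
                     21.71, 41.23, 26.11, 10.95,
                     18.09, 42.54, 30.14, 9.24,
                     18.01, 45.64, 29.29, 7.06)),
    cdist_sd = m(c(0.32, 1.27, 4.02, 1.84,
                   3.74, 4.49, 2.83, 7.71,
                   0.65, 2.15, 2.57, 0.98,
                   3.47, 6.37, 6.57, 1.01,
                   4.44, 4.66, 0.26, 0.56,
                   3.85, 2.63, 4.33, 1.87,
                   0.23, 5.68, 5.14, 0.74)),
    r025_soc_mean = stats::setNames(
      c(38.56, 46.13, 45.54, 52.86, 62.93, 60.63, 63.65), tr),
    r025_soc_sd = stats::setNames(
      c(4.29, 3.68, 1.61, 2.21, 0.34, 6.15, 5.67), tr),
    total_soc_mean = stats::setNames(
      c(16.43, 21.18, 20.84, 20.42, 21.18, 21.26, 21.19), tr),
    total_soc_sd = stats::setNames(
      c(0.87, 0.99, 0.19, 0.52, 0.88, 0.60, 0.39), tr),
    groups = list(Group1 = c("MI1", "MI2"),
                  Group2 = c("MI3", "MI4", "MI5", "MI6"))
  )
}
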