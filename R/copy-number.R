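# qPCR relative quantification and the cell-cycle copy-number model.
#
# The model: in an exponentially growing culture a cell at cell-cycle stage
# x (0 = newborn, 1 = dividing) carries p(x) = m * 2^x plasmids, copy number
# doubling smoothly over the cycle. The steady-state age distribution of an
# exponential culture weights young cells more, with density
# f(x) = 2 ln2 * 2^(-x) on [0, 1]; requiring the population average of p(x)
# to equal the measured culture average k fixes m = k / (2 ln 2). With the
# measured k = 17 this gives ~12 plasmids at birth and ~24 at division.

#' Plasmid:oriC ratio from a qPCR plate
#'
#' Efficiency-corrected delta-delta-Ct quantification of plasmid copies
#' relative to the chromosomal *oriC* region:
#' `ratio = eff_pl^(ct_cal_pl - ct_pl) / eff_chr^(ct_cal_chr - ct_chr) *
#' calibrator_ratio`, using the mean Ct per target class. The result is
#' invariant to adding a constant to every Ct (it is calibrator-relative).
#'
#' @param plate a `qpcr_plate` (see [gen_qpcr_plate()]) or any data frame
#'   with columns `target` (`chr`, `pl`, `cal_chr`, `cal_pl`) and `ct`.
#' @param eff_chr,eff_pl amplification efficiencies (fold/cycle, `(1, 2]`);
#'   defaults taken from the plate attributes, else 2 (perfect doubling).
#' @param calibrator_ratio known plasmid:chromosome ratio of the calibrator
#'   template (default 1, equal template).
#' @return Scalar plasmid:oriC copy ratio.
#' @examples
#' plate <- gen_qpcr_plate(true_ratio = 8, ct_noise_sd = 0, n_replicates = 2)
#' qpcr_ratio(plate) # 8
#' @export
qpcr_ratio <- function(plate, eff_chr = NULL, eff_pl = NULL,
                       calibrator_ratio = 1) {
  if (!all(c("target", "ct") %in% names(plate)))
    stop("plate needs 'target' and 'ct' columns", call. = FALSE)
  eff_chr <- eff_chr %||% attr(plate, "eff_chr") %||% 2
  eff_pl <- eff_pl %||% attr(plate, "eff_pl") %||% 2
  check_num(eff_chr, "eff_chr", lower = 1, upper = 2, strict_lower = TRUE)
  check_num(eff_pl, "eff_pl", lower = 1, upper = 2, strict_lower = TRUE)
  need <- c("chr", "pl", "cal_chr", "cal_pl")
  miss <- setdiff(need, unique(plate$target))
  if (length(miss))
    stop("plate is missing wells for target(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- vapply(need, function(tg) mean(plate$ct[plate$target == tg]), 0)
  unname(eff_pl^(m["cal_pl"] - m["pl"]) / eff_chr^(m["cal_chr"] - m["chr"]) *
           calibrator_ratio)
}

#' Plasmids per cell from a relative ratio
#'
#' Multiplies the plasmid:oriC copy ratio by the average number of *oriC*
#' per cell in the growth condition. With the measured ratio and 1.9 oriC
#' per cell this route gives ~17 plasmids per cell; the CFU-based route
#' (2.6 oriC per cell) gives ~24.
#'
#' @param ratio plasmid:oriC copy ratio, `> 0`.
#' @param oric_avg mean oriC copies per cell, `> 0`.
#' @return Plasmids per cell.
#' @examples
#' plasmids_per_cell(8.95, 1.9) # ~17
#' @export
plasmids_per_cell <- function(ratio, oric_avg) {
  check_num(ratio, "ratio", lower = 0, strict_lower = TRUE)
  check_num(oric_avg, "oric_avg", lower = 0, strict_lower = TRUE)
  ratio * oric_avg
}

#' Average oriC copies per cell in exponential growth
#'
#' For a culture with generation time `tau_gen` and replication/division
#' periods C and D, the population-mean number of replication origins is
#' `2^((C + D) / tau_gen)` (exponential-culture origin formula). The
#' defaults, C + D = 92.6 min at tau_gen = 100 min, reproduce the 1.9 oriC
#' per cell of slow growth in minimal glycerol medium.
#'
#' @param tau_gen generation time (min).
#' @param C replication period (min).
#' @param D post-replication division period (min).
#' @return Mean oriC per cell.
#' @examples
#' oric_average(100, C = 50, D = 42.6) # 1.90
#' @export
oric_average <- function(tau_gen = 100, C = 50, D = 42.6) {
  check_num(tau_gen, "tau_gen", lower = 0, strict_lower = TRUE)
  check_num(C, "C", lower = 0)
  check_num(D, "D", lower = 0)
  2^((C + D) / tau_gen)
}

#' Cell-cycle plasmid copy number
#'
#' `p(x) = (k / (2 ln 2)) * 2^x`: the copy number of a cell at cell-cycle
#' stage `x` implied by a population-average copy number `k`, with the
#' normalising constant fixed by the steady-state exponential-culture age
#' distribution (see [population_average()]). `p(1) = 2 p(0)` always.
#'
#' @param k population-average plasmids per cell, `> 0`.
#' @param x cell-cycle stage(s) in `[0, 1]` (0 newborn, 1 dividing).
#' @return Copy number(s) `p(x)`.
#' @examples
#' cycle_copy_number(17, c(0, 1)) # ~12 at birth, ~24 at division
#' @export
cycle_copy_number <- function(k, x) {
  check_num(k, "k", lower = 0, strict_lower = TRUE)
  x <- as.numeric(x)
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  (k / (2 * log(2))) * 2^x
}

#' Population-average copy number from the newborn copy number
#'
#' Closure of the cell-cycle model: averaging `p0 * 2^x` over the
#' steady-state age density `f(x) = 2 ln2 * 2^(-x)` gives
#' `k = p0 * 2 ln 2`. Exact inverse of [cycle_copy_number()] at `x = 0`.
#'
#' @param p0 newborn copy number, `> 0`.
#' @return Population-average copy number `k`.
#' @examples
#' population_average(12.26) # ~17
#' @export
population_average <- function(p0) {
  check_num(p0, "p0", lower = 0, strict_lower = TRUE)
  p0 * 2 * log(2)
}
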