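#' Encapsulation efficiency of a nanoparticle batch
#'
#' Fraction of the loaded drug associated with the nanoparticle phase,
#' computed from the total drug mass used in the preparation and the free
#' drug mass assayed in the supernatant after ultracentrifugation:
#' \code{EE = (M_t - M_s) / M_t}.
#'
#' @param total_mass Total drug mass used for the preparation (mg), > 0.
#' @param supernatant_mass Drug mass found in the supernatant (mg), in
#'   \code{[0, total_mass]}.
#' @return Encapsulation efficiency as a fraction in \code{[0, 1]}. Percent
#'   rendering (x100) belongs to the reporting layer.
#' @examples
#' encapsulation_efficiency(6.25, 5.275) # 0.156
#' @export
encapsulation_efficiency <- function(total_mass, supernatant_mass) {
  check_number(total_mass, "total_mass", lower = 0, strict_lower = TRUE)
  check_number(supernatant_mass, "supernatant_mass", lower = 0)
  if (supernatant_mass > total_mass)
    stop_ocunano(
      "supernatant drug mass exceeds total loaded mass: assay inconsistency",
      "ocunano_domain_error")
  (total_mass - supernatant_mass) / total_mass
}

#' Split a drug dose into entrapped and free mass
#'
#' Partitions a total dose between the nanoparticle-entrapped pool and the
#' free (dispersion-medium) pool according to the encapsulation efficiency.
#' The free fraction matters in vivo: drug not entrapped in nanoparticles
#' permeates the cornea by passive diffusion regardless of particle surface
#' chemistry.
#'
#' @param total_mass Total drug mass (mg), >= 0.
#' @param ee Encapsulation efficiency, fraction in \code{[0, 1]}.
#' @return A \code{dose_split} list with \code{total_mass},
#'   \code{entrapped_mass} and \code{free_mass} (mg); the two pools sum to
#'   the total exactly.
#' @examples
#' dose_split(6.25, 0.16)
#' @export
dose_split <- function(total_mass, ee) {
  check_number(total_mass, "total_mass", lower = 0)
  check_number(ee, "ee", lower = 0, upper = 1)
  entrapped <- ee * total_mass
  structure(
    list(total_mass = total_mass,
         entrapped_mass = entrapped,
         free_mass = total_mass - entrapped),
    class = "dose_split")
}

#' @export
print.dose_split <- function(x, ...) {
  cat(sprintf("Dose split: total %.4g mg = entrapped %.4g mg + free %.4g mg\n",
              x$total_mass, x$entrapped_mass, x$free_mass))
  invisible(x)
}

#' Construct a nanoparticle batch descriptor
#'
#' Bookkeeping record for one medicated nanoparticle batch: hydrodynamic
#' size, polydispersity index, zeta potential and encapsulation efficiency.
#' These are measured quantities (DLS / ELS / UV assay) consumed as fixtures
#' by downstream stages; the package never recomputes them.
#'
#' @param label Batch label, e.g. \code{"NP QA-Ch"}.
#' @param size_nm Z-average hydrodynamic diameter (nm), > 0.
#' @param pdi Polydispersity index in \code{[0, 1]}.
#' @param zeta_mV Zeta potential (mV); positive for quaternary-ammonium
#'   chitosan particles, negative for sulfobutyl chitosan.
#' @param ee Encapsulation efficiency as a fraction in \code{[0, 1]}.
#' @return An \code{np_batch} list.
#' @export
np_batch <- function(label, size_nm, pdi, zeta_mV, ee) {
  stopifnot(is.character(label), length(label) == 1L)
  check_number(size_nm, "size_nm", lower = 0, strict_lower = TRUE)
  check_number(pdi, "pdi", lower = 0, upper = 1)
  check_number(zeta_mV, "zeta_mV")
  check_number(ee, "ee", lower = 0, upper = 1)
  structure(list(label = label, size_nm = size_nm, pdi = pdi,
                 zeta_mV = zeta_mV, ee = ee),
            class = "np_batch")
}

#' @export
print.np_batch <- function(x, ...) {
  cat(sprintf("NP batch %s: %.0f nm (PDI %.2f), zeta %+.1f mV, EE %.1f%%\n",
              x$label, x$size_nm, x$pdi, x$zeta_mV, 100 * x$ee))
  invisible(x)
}

#' Read a nanoparticle batch fixture table
#'
#' Reads a CSV of measured batch characteristics with columns
#' \code{label,size_nm,pdi,zeta_mV,ee_pct} (EE in percent, as printed in
#' study reports) and returns a list of [np_batch] records. The packaged
#' fixture holds the three study batches.
#'
#' @param path CSV path; defaults to the fixture shipped with the package.
#' @return Named list of \code{np_batch} objects.
#' @examples
#' batches <- read_np_batches()
#' batches[["NP SB-Ch"]]
#' @export
read_np_batches <- function(path = system.file("extdata", "np_batches.csv",
                                               package = "ocunano")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("label", "size_nm", "pdi", "zeta_mV", "ee_pct")
  if (!all(needed %in% names(df)))
    stop_ocunano(sprintf("batch fixture must have columns %s",
                         paste(needed, collapse = ",")),
                 "ocunano_input_error")
  out <- lapply(seq_len(nrow(df)), function(i)
    np_batch(df$label[i], df$size_nm[i], df$pdi[i], df$zeta_mV[i],
             df$ee_pct[i] / 100))
  names(out) <- df$label
  out
}
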