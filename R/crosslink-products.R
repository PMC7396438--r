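## Stoichiometry arithmetic for cross-linked products: predicted adduct
## masses and internal-control-normalised band quantification.

#' Default species masses (kDa)
#'
#' Approximate monomer masses of the proteins handled by the docking
#' pipeline: BamA ~95 kDa, SurA ~47 kDa, BamB ~40 kDa. Override freely or
#' load from a YAML mapping with \code{\link{readSpeciesMasses}}.
#'
#' @export
speciesMasses <- function() c(BamA = 95, SurA = 47, BamB = 40)

#' Read species masses from a YAML mapping
#' @param path YAML file of name: mass_kDa pairs.
#' @export
readSpeciesMasses <- function(path) {
  unlist(yaml::read_yaml(path))
}

#' Predicted molecular mass of a cross-linked adduct
#'
#' Linear in the stoichiometry: the sum over species of count times
#' monomer mass. A 1:1 adduct of a 95 and a 47 kDa protein is 142 kDa; a
#' 1:2 adduct 189 kDa.
#'
#' @param stoichiometry named numeric of species counts (>= 0, not all
#'   zero).
#' @param masses named numeric of monomer masses, kDa (default
#'   \code{\link{speciesMasses}()}).
#' @return predicted mass in kDa.
#' @export
predictedMass <- function(stoichiometry, masses = speciesMasses()) {
  if (length(stoichiometry) == 0)
    stop("empty stoichiometry")
  if (any(stoichiometry < 0) || all(stoichiometry == 0))
    stop("stoichiometry counts must be non-negative and not all zero")
  miss <- setdiff(names(stoichiometry), names(masses))
  if (length(miss) > 0)
    stop("no mass for species: ", paste(miss, collapse = ", "))
  sum(stoichiometry * masses[names(stoichiometry)])
}

#' Internal-control-normalised band amounts
#'
#' Each band intensity is divided by its lane's internal-control
#' intensity, and the resulting ratios are scaled so the reference lane
#' maps to 1.00 -- making the amounts invariant to global intensity
#' rescaling and to the choice of units.
#'
#' @param measurements data.frame(lane, band, control) with non-negative
#'   band and positive control intensities.
#' @param reference lane label of the reference lane.
#' @return data.frame(lane, amount).
#' @export
normalizeBands <- function(measurements, reference) {
  stopifnot(all(c("lane", "band", "control") %in% names(measurements)))
  if (any(measurements$control <= 0))
    stop("measurement error: internal control intensity must be positive")
  if (any(measurements$band < 0))
    stop("measurement error: band intensities must be non-negative")
  if (!reference %in% measurements$lane)
    stop("reference lane not present: ", reference)
  ratio <- measurements$band / measurements$control
  ref <- ratio[match(reference, measurements$lane)]
  if (ref <= 0) stop("reference lane has zero band intensity")
  data.frame(lane = measurements$lane, amount = ratio / ref,
             stringsAsFactors = FALSE)
}

#' Average replicate band amounts
#'
#' Replicate measurements of the same band are averaged and reported with
#' the standard deviation; the individual replicate values are retained.
#'
#' @param amounts data.frame(band, replicate, amount).
#' @return data.frame(band, mean, sd, n, values).
#' @export
summarizeBands <- function(amounts) {
  stopifnot(all(c("band", "amount") %in% names(amounts)))
  out <- do.call(rbind, lapply(split(amounts, amounts$band), function(d) {
    data.frame(band = d$band[1L], mean = mean(d$amount),
               sd = stats::sd(d$amount), n = nrow(d),
               values = paste(format(d$amount), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sum of band amounts
#'
#' The total amount carried by a set of cross-linked products (e.g. the
#' two products of a dual cross-linking experiment); an empty input sums
#' to zero.
#'
#' @param amounts numeric vector.
#' @export
sumAmounts <- function(amounts) sum(amounts)
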