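#' Construct the standard Littorina sample sheet
#'
#' Nine groups of snails are hybridized: *L. fabalis* (Sweden), *L. compressa*
#' (Britain), *L. arcana* (Britain), and *L. saxatilis* Crab and Wave ecotypes
#' from each of Britain, Spain and Sweden, with `n_per_group` individuals per
#' group. Within each group half the samples are labeled Cy3 and half Cy5;
#' each subarray hosts exactly two samples of opposite dye, paired across
#' groups so dye and subarray are not confounded with the biology.
#'
#' @param n_per_group Individuals per group (even, default 4).
#' @param subarrays_per_slide Physical subarrays per slide (layout bookkeeping
#'   only).
#' @return Data frame with columns `sample_id`, `species`, `population`,
#'   `ecotype`, `dye`, `subarray`, `slide`.
#' @export
littorina_sample_sheet <- function(n_per_group = 4L, subarrays_per_slide = 12L) {
  if (n_per_group %% 2L != 0L)
    stop("n_per_group must be even so dyes balance within groups")
  groups <- data.frame(
    species    = c("fabalis", "compressa", "arcana", rep("saxatilis", 6L)),
    population = c("Sweden", "Britain", "Britain",
                   "Britain", "Britain", "Spain", "Spain", "Sweden", "Sweden"),
    ecotype    = c("none", "none", "none",
                   "wave", "crab", "wave", "crab", "wave", "crab"),
    stringsAsFactors = FALSE)
  sheet <- groups[rep(seq_len(nrow(groups)), each = n_per_group), ]
  sheet$dye <- rep(rep(c("Cy3", "Cy5"), each = n_per_group / 2L),
                   times = nrow(groups))
  sheet$sample_id <- sprintf("%s_%s_%s_%d", sheet$species, sheet$population,
                             sheet$ecotype,
                             rep(seq_len(n_per_group), nrow(groups)))
  rownames(sheet) <- NULL
  # Pair the i-th Cy3 sample with a Cy5 sample shifted by one group, so no
  # subarray carries two samples of the same group or the same dye.
  cy3 <- which(sheet$dye == "Cy3")
  cy5 <- which(sheet$dye == "Cy5")
  shift <- n_per_group / 2L
  cy5 <- c(cy5[-seq_len(shift)], cy5[seq_len(shift)])
  sheet$subarray <- NA_integer_
  sheet$subarray[cy3] <- seq_along(cy3)
  sheet$subarray[cy5] <- seq_along(cy5)
  sheet$slide <- (sheet$subarray - 1L) %/% subarrays_per_slide + 1L
  sheet[, c("sample_id", "species", "population", "ecotype", "dye",
            "subarray", "slide")]
}

#' Validate a sample sheet
#'
#' Checks the hybridization design constraints: dyes balanced within every
#' group and every subarray hosting exactly two samples of opposite dye.
#'
#' @param sheet A sample sheet data frame.
#' @return `sheet` invisibly; errors describe the violated constraint.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "species", "population", "ecotype", "dye", "subarray")
  missing <- setdiff(req, names(sheet))
  if (length(missing) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample ids")
  if (!all(sheet$dye %in% c("Cy3", "Cy5")))
    stop("dye must be Cy3 or Cy5")
  grp <- sample_groups(sheet)
  bal <- tapply(sheet$dye, grp, function(d) sum(d == "Cy3") == sum(d == "Cy5"))
  if (!all(bal))
    stop("dye not balanced within group(s): ",
         paste(names(bal)[!bal], collapse = ", "))
  per_sub <- split(sheet$dye, sheet$subarray)
  ok <- vapply(per_sub, function(d)
    length(d) == 2L && sum(d == "Cy3") == 1L, logical(1L))
  if (!all(ok))
    stop("subarray(s) without exactly one Cy3 and one Cy5 sample: ",
         paste(names(per_sub)[!ok], collapse = ", "))
  invisible(sheet)
}

#' Group labels from a sample sheet
#'
#' `sample_groups()` returns the full species x population x ecotype label
#' (the experimental group); `geo_groups()` the species x population label
#' (the unit at which genome truth is defined -- ecotypes of one population
#' share a genome-level state).
#'
#' @param sheet A sample sheet data frame.
#' @return Character vector, one label per sample.
#' @export
sample_groups <- function(sheet) {
  paste(sheet$species, sheet$population, sheet$ecotype, sep = "_")
}

#' @rdname sample_groups
#' @export
geo_groups <- function(sheet) {
  paste(sheet$species, sheet$population, sep = "_")
}

#' Write / read a sample sheet as CSV
#' @param sheet A sample sheet data frame.
#' @param path CSV path.
#' @return The path (write) or the sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
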