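# On-disk cohort layout:
#   manifest.json            cohort-level metadata + per-study entries
#   volumes/<study>.nii.gz   int16 NIfTI volume per study
#   slice_labels.csv         study_id, slice_index, label
#   emr_<category>.csv       per-category EMR rows, keyed by study_id
# EMR times are day offsets relative to each study's CT exam (day 0);
# 24 hours = 1 day.

.MANIFEST_SCHEMA_VERSION <- "1.0"
.MANIFEST_KNOWN_FIELDS <- c("schema_version", "package", "spec", "studies")

.specToList <- function(spec) {
  list(nPatients = spec@nPatients,
       studiesPerPatientMax = spec@studiesPerPatientMax,
       prevalence = spec@prevalence,
       slicesPerStudy = spec@slicesPerStudy,
       volumeShape = spec@volumeShape,
       imageEffect = spec@imageEffect,
       emrEffect = as.list(spec@emrEffect),
       emrNoiseSd = spec@emrNoiseSd,
       missingness = as.list(spec@missingness),
       subsegmentalFraction = spec@subsegmentalFraction,
       subsegmentalAttenuation = spec@subsegmentalAttenuation,
       splitFractions = spec@splitFractions,
       seed = spec@seed)
}

.specFromList <- function(x) {
  cohortSpec(nPatients = x$nPatients,
             studiesPerPatientMax = x$studiesPerPatientMax,
             prevalence = x$prevalence,
             slicesPerStudy = unlist(x$slicesPerStudy),
             volumeShape = unlist(x$volumeShape),
             imageEffect = x$imageEffect,
             emrEffect = unlist(x$emrEffect),
             emrNoiseSd = x$emrNoiseSd,
             missingness = unlist(x$missingness),
             subsegmentalFraction = x$subsegmentalFraction,
             subsegmentalAttenuation = x$subsegmentalAttenuation,
             splitFractions = unlist(x$splitFractions),
             seed = x$seed)
}

#' Write a cohort to disk
#'
#' Serialises a [PECohort-class] as a JSON manifest, one int16 NIfTI volume
#' per study, a global slice-label CSV, and one CSV per EMR category.
#' Categories missing for a study (recorded as `NULL` in memory) are marked
#' in the manifest so that [readCohort()] reproduces them exactly.
#'
#' @param cohort A [PECohort-class].
#' @param directory Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "PECohort"))
  dir.create(file.path(directory, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  sliceRows <- list()
  emrRows <- stats::setNames(vector("list", length(emrCategories())),
                             emrCategories())
  entries <- list()
  for (st in cohort@studies) {
    volFile <- file.path("volumes", paste0(st@studyId, ".nii.gz"))
    img <- RNifti::asNifti(st@volume, datatype = "int16")
    RNifti::writeNifti(img, file.path(directory, volFile))
    sliceRows[[st@studyId]] <- data.frame(
      study_id = st@studyId,
      slice_index = seq_along(st@sliceLabels),
      label = st@sliceLabels)
    present <- !vapply(st@emr, is.null, logical(1))
    for (cat in emrCategories()) {
      if (!present[[cat]]) next
      tab <- st@emr[[cat]]
      if (nrow(tab) > 0)
        emrRows[[cat]] <- c(emrRows[[cat]],
                            list(cbind(study_id = st@studyId, tab)))
    }
    entries[[st@studyId]] <- list(
      study_id = st@studyId, patient_id = st@patientId, split = st@split,
      label = st@label, pe_extent = st@peExtent,
      n_slices = length(st@sliceLabels), encounter_id = st@encounterId,
      volume_file = volFile, emr_present = as.list(present))
  }
  utils::write.csv(do.call(rbind, sliceRows),
                   file.path(directory, "slice_labels.csv"),
                   row.names = FALSE)
  for (cat in emrCategories()) {
    tab <- if (length(emrRows[[cat]])) do.call(rbind, emrRows[[cat]])
           else cbind(study_id = character(), .emptyEMRTable(cat))
    utils::write.csv(tab, file.path(directory,
                                    sprintf("emr_%s.csv", cat)),
                     row.names = FALSE)
  }
  manifest <- list(schema_version = .MANIFEST_SCHEMA_VERSION,
                   package = "fusePE",
                   spec = .specToList(cohort@spec),
                   studies = unname(entries))
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Inverse of [writeCohort()]: reproduces labels, splits, integer volumes
#' (bit-exact) and EMR tables, including which categories are missing per
#' study. Unknown manifest fields are ignored with a warning (forward
#' compatibility); a missing manifest or a schema-version mismatch is an
#' error.
#'
#' @param directory Directory written by [writeCohort()].
#' @return A [PECohort-class].
#' @export
readCohort <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path))
    stop("cohort manifest not found: ", path)
  manifest <- jsonlite::read_json(path)
  unknown <- setdiff(names(manifest), .MANIFEST_KNOWN_FIELDS)
  if (length(unknown))
    warning("ignoring unknown manifest field(s): ",
            paste(unknown, collapse = ", "))
  if (!identical(manifest$schema_version, .MANIFEST_SCHEMA_VERSION))
    stop("manifest schema version ", manifest$schema_version,
         " does not match supported version ", .MANIFEST_SCHEMA_VERSION)
  spec <- .specFromList(manifest$spec)
  sliceTab <- utils::read.csv(file.path(directory, "slice_labels.csv"))
  emrTabs <- lapply(stats::setNames(emrCategories(), emrCategories()),
    function(cat) {
      f <- file.path(directory, sprintf("emr_%s.csv", cat))
      if (file.exists(f))
        utils::read.csv(f, stringsAsFactors = FALSE,
                        colClasses = c(study_id = "character"))
      else NULL
    })
  studies <- lapply(manifest$studies, function(e) {
    vol <- RNifti::readNifti(file.path(directory, e$volume_file))
    vol <- array(as.integer(vol), dim = dim(vol))
    sl <- sliceTab[sliceTab$study_id == e$study_id, ]
    sl <- sl[order(sl$slice_index), ]
    emr <- list()
    for (cat in emrCategories()) {
      if (isTRUE(e$emr_present[[cat]])) {
        tab <- emrTabs[[cat]]
        tab <- tab[tab$study_id == e$study_id, , drop = FALSE]
        tab$study_id <- NULL
        rownames(tab) <- NULL
        if (nrow(tab) == 0) tab <- .emptyEMRTable(cat)
        emr[[cat]] <- tab
      } else {
        emr[cat] <- list(NULL)
      }
    }
    new("SyntheticStudy",
        patientId = e$patient_id, studyId = e$study_id, split = e$split,
        label = as.integer(e$label), peExtent = e$pe_extent,
        sliceLabels = as.integer(sl$label), volume = vol,
        emr = emr[emrCategories()], encounterId = e$encounter_id)
  })
  new("PECohort", studies = studies, spec = spec)
}
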