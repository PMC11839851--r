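# Cohort serialization ---------------------------------------------------
#
# One NIfTI file per instance plus plain-text sidecars: instances.csv
# (instance metadata + file name), scans.csv (severity, true class),
# votes.csv (one column per reader) and cohort.json (profile and
# geometry needed to rebuild the container).

#' Write a cohort to disk
#'
#' @param cohort a [SlabCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  inst <- instanceInfo(cohort)
  files <- file.path("images", paste0(inst$instance_id, ".nii.gz"))
  pix <- cohort@config$pixelSizeMm %||% 3
  for (i in seq_len(nrow(inst))) {
    RNifti::writeNifti(
      RNifti::asNifti(cohort@images[, , i], pixdim = c(pix, pix)),
      file.path(dir, files[i]))
  }
  inst$file <- files
  write.csv(inst, file.path(dir, "instances.csv"), row.names = FALSE)
  write.csv(scanInfo(cohort), file.path(dir, "scans.csv"),
            row.names = FALSE)
  votes <- as.data.frame(readerVotes(cohort))
  votes <- cbind(scan_id = rownames(readerVotes(cohort)), votes)
  write.csv(votes, file.path(dir, "votes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(profile = cohort@profile, pixelSizeMm = pix,
         imageSize = dim(cohort@images)[1]),
    file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir the cohort directory.
#' @return a [SlabCohort-class].
#' @export
readCohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  inst <- read.csv(file.path(dir, "instances.csv"),
                   stringsAsFactors = FALSE)
  scans <- read.csv(file.path(dir, "scans.csv"), stringsAsFactors = FALSE)
  votesDf <- read.csv(file.path(dir, "votes.csv"),
                      stringsAsFactors = FALSE)
  votes <- as.matrix(votesDf[, -1, drop = FALSE])
  storage.mode(votes) <- "integer"
  rownames(votes) <- votesDf$scan_id
  images <- array(0, c(meta$imageSize, meta$imageSize, nrow(inst)))
  for (i in seq_len(nrow(inst)))
    images[, , i] <- as.matrix(RNifti::readNifti(file.path(dir,
                                                           inst$file[i])))
  inst$file <- NULL
  new("SlabCohort", images = images, instances = inst, scans = scans,
      votes = votes, profile = meta$profile,
      config = list(pixelSizeMm = meta$pixelSizeMm))
}
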