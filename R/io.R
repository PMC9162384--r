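#' Write / read a cohort directory
#'
#' On-disk layout (all plain text):
#' \itemize{
#'   \item `features_<METRIC>.tsv` — one row per subject; columns
#'     `subject_id`, `group`, then one column per region label
#'   \item `fc/<subject_id>.txt` — whitespace-delimited R x R matrix
#'   \item `clinical.tsv`
#'   \item `cohort.json` — sidecar with the spec, seed and spec digest
#' }
#'
#' @param cohort a `synthetic_cohort` (or compatible list)
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(cohort$tables))
    write_regional_table(cohort$tables[[m]],
                         file.path(dir, paste0("features_", m, ".tsv")))
  fcdir <- file.path(dir, "fc")
  dir.create(fcdir, showWarnings = FALSE)
  for (s in names(cohort$fc))
    write.table(format(cohort$fc[[s]], digits = 17),
                file.path(fcdir, paste0(s, ".txt")),
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$log, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param table a [regional_table]
#' @param path file path
#' @export
write_regional_table <- function(table, path) {
  df <- data.frame(subject_id = table$subjects,
                   group = as.character(table$groups),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param metric metric id recorded on the returned table
#' @export
read_regional_table <- function(path, metric = NA_character_) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "group")),
                       drop = FALSE])
  rownames(vals) <- df$subject_id
  regional_table(vals, metric = metric, groups = df$group)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  feat_files <- list.files(dir, pattern = "^features_.*\\.tsv$")
  tables <- list()
  for (f in feat_files) {
    m <- sub("^features_(.*)\\.tsv$", "\\1", f)
    tables[[m]] <- read_regional_table(file.path(dir, f), metric = m)
  }
  tables <- tables[intersect(METRICS, names(tables))]
  clinical <- read.delim(file.path(dir, "clinical.tsv"),
                         stringsAsFactors = FALSE)
  clinical$group <- factor(clinical$group, levels = c("patient", "control"))
  clinical$gender <- factor(clinical$gender, levels = c("M", "F"))
  subjects <- tables[[1]]$subjects
  fcdir <- file.path(dir, "fc")
  fc <- NULL
  if (dir.exists(fcdir)) {
    fc <- lapply(subjects, function(s) {
      m <- as.matrix(read.table(file.path(fcdir, paste0(s, ".txt"))))
      dimnames(m) <- list(colnames(tables[[1]]$values),
                          colnames(tables[[1]]$values))
      m
    })
    names(fc) <- subjects
  }
  log <- NULL
  if (file.exists(file.path(dir, "cohort.json")))
    log <- jsonlite::fromJSON(file.path(dir, "cohort.json"))
  structure(list(tables = tables, fc = fc, timeseries = NULL,
                 clinical = clinical, subjects = subjects,
                 groups = tables[[1]]$groups, log = log),
            class = "synthetic_cohort")
}
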