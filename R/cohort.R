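#' Construct a subject record
#'
#' One study participant: identifier, age in years, sex, acquisition site and
#' the subject's connectome. Sex is stored as given (`"female"`/`"male"`,
#' abbreviations accepted) and encoded internally as female = 1, male = 0.
#'
#' @param subject_id character scalar, unique within a cohort.
#' @param age age in years, finite, in (0, 120).
#' @param sex `"female"`/`"male"` (or `"F"`/`"M"`, case-insensitive).
#' @param site site label.
#' @param connectome a [connectome()] (may be `NULL` for metadata-only use).
#' @return an object of class `"subject_record"`.
#' @export
subject_record <- function(subject_id, age, sex, site, connectome = NULL) {
  if (!is.numeric(age) || !is.finite(age) || age <= 0 || age >= 120)
    stop(sprintf("subject %s: age must be finite and in (0, 120), got %s",
                 subject_id, format(age)), call. = FALSE)
  sex <- normalize_sex(sex, subject_id)
  if (!is.null(connectome)) stopifnot(is_connectome(connectome))
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 sex = sex, site = as.character(site),
                 connectome = connectome),
            class = "subject_record")
}

normalize_sex <- function(sex, subject_id = "<unknown>") {
  token <- tolower(as.character(sex))
  if (token %in% c("female", "f")) return("female")
  if (token %in% c("male", "m")) return("male")
  stop(sprintf("subject %s: unknown sex token '%s' (expected female/male)",
               subject_id, sex), call. = FALSE)
}

#' Numeric sex encoding used by the model (female = 1, male = 0)
#' @param sex character vector of sex labels.
#' @return numeric 0/1 vector.
#' @export
encode_sex <- function(sex) {
  as.numeric(vapply(sex, normalize_sex, character(1)) == "female")
}

#' Construct a cohort
#'
#' A cohort bundles subject records whose connectomes share a parcellation
#' (same node count and labels). The site vocabulary is the sorted set of
#' observed site labels unless supplied explicitly.
#'
#' @param records list of [subject_record()] objects.
#' @param site_vocabulary optional ordered character vector of site labels.
#' @return an object of class `"cohort"`.
#' @export
cohort <- function(records, site_vocabulary = NULL) {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  conns <- Filter(Negate(is.null), lapply(records, function(r) r$connectome))
  if (length(conns) > 1) {
    n0 <- conns[[1]]$n
    lab0 <- conns[[1]]$node_labels
    for (cn in conns[-1]) {
      if (cn$n != n0 || !identical(cn$node_labels, lab0))
        stop("all connectomes in a cohort must share node count and labels",
             call. = FALSE)
    }
  }
  sites <- vapply(records, function(r) r$site, character(1))
  if (is.null(site_vocabulary)) {
    site_vocabulary <- sort(unique(sites))
  } else if (!all(sites %in% site_vocabulary)) {
    stop("some records carry sites outside the declared site vocabulary",
         call. = FALSE)
  }
  structure(list(records = records,
                 site_vocabulary = as.character(site_vocabulary)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  sites <- vapply(x$records, function(r) r$site, character(1))
  cat(sprintf("<cohort> %d subjects across %d site(s): %s\n",
              length(x$records), length(x$site_vocabulary),
              paste(sprintf("%s (n=%d)", x$site_vocabulary,
                            tabulate(factor(sites, x$site_vocabulary))),
                    collapse = ", ")))
  invisible(x)
}

#' Cohort metadata as a data frame
#' @param x a `"cohort"`.
#' @return data.frame with columns `subject_id`, `age`, `sex`, `site`.
#' @export
cohort_metadata <- function(x) {
  stopifnot(inherits(x, "cohort"))
  data.frame(
    subject_id = vapply(x$records, function(r) r$subject_id, character(1)),
    age = vapply(x$records, function(r) r$age, numeric(1)),
    sex = vapply(x$records, function(r) r$sex, character(1)),
    site = vapply(x$records, function(r) r$site, character(1)),
    stringsAsFactors = FALSE)
}

#' Read a cohort from a metadata table plus a directory of matrices
#'
#' The metadata file is TSV/CSV with header columns `subject_id`, `age`,
#' `sex`, `site`. Each subject's connectome is read from
#' `<connectome_dir>/<subject_id>.csv` (or `.tsv`/`.txt`). All connectomes are
#' validated on load; missing files are reported together by subject id.
#'
#' @param metadata_path path to the metadata TSV/CSV.
#' @param connectome_dir directory of per-subject connectome matrices.
#' @return a [cohort()] whose `site_vocabulary` is the sorted set of observed
#'   sites.
#' @export
read_cohort <- function(metadata_path, connectome_dir) {
  if (!file.exists(metadata_path))
    stop(sprintf("metadata file not found: %s", metadata_path), call. = FALSE)
  first <- readLines(metadata_path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  md <- utils::read.table(metadata_path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("subject_id", "age", "sex", "site")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop(sprintf("metadata is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)

  paths <- vapply(as.character(md$subject_id), function(id) {
    for (ext in c(".csv", ".tsv", ".txt")) {
      p <- file.path(connectome_dir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(paths))
    stop(sprintf("no connectome file found for subject(s): %s",
                 paste(md$subject_id[is.na(paths)], collapse = ", ")),
         call. = FALSE)

  records <- lapply(seq_len(nrow(md)), function(i)
    subject_record(md$subject_id[i], md$age[i], md$sex[i], md$site[i],
                   read_connectome(paths[i])))
  cohort(records)
}

#' Write a cohort to disk (metadata TSV + per-subject matrices)
#'
#' Inverse of [read_cohort()]; used by the synthetic generator and the
#' command-line interface.
#'
#' @param x a [cohort()].
#' @param dir output directory (created if needed); matrices are written as
#'   `<subject_id>.csv`, metadata as `metadata.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort_metadata(x), file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (r in x$records)
    write_connectome(r$connectome, file.path(dir, paste0(r$subject_id, ".csv")))
  invisible(dir)
}

#' Subset a cohort by site
#' @param x a [cohort()].
#' @param site site label(s) to keep.
#' @return a [cohort()] (site vocabulary preserved).
#' @export
cohort_subset <- function(x, site) {
  stopifnot(inherits(x, "cohort"))
  keep <- vapply(x$records, function(r) r$site %in% site, logical(1))
  cohort(x$records[keep], site_vocabulary = x$site_vocabulary)
}
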