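#' Toxicity dataset container
#'
#' A `toxicity_dataset` couples the per-compound endpoint table (green-algae
#' pEC50, bacterial-genotoxicity pLOEC, composite characterization value Z,
#' train/test split) with an optional map of molecular structures.
#'
#' @param records data.frame with columns `compound_id`, `name`, `p_ec50`,
#'   `p_loec`, optional `composite`, `split` (`"train"`/`"test"`), `flag`
#' @param molecules optional named list of structures (names = compound ids)
#' @param provenance free-text description of where the records came from
#' @return an object of class `toxicity_dataset`
#' @export
toxicity_dataset <- function(records, molecules = NULL, provenance = "") {
  stopifnot(is.data.frame(records))
  required <- c("compound_id", "name", "p_ec50", "p_loec")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop_duotox("records missing columns: ", paste(missing, collapse = ", "),
                class = "duotox_schema_error")
  }
  if (anyDuplicated(records$compound_id)) {
    stop_duotox("compound_id values must be unique", class = "duotox_integrity_error")
  }
  if (!all(is.finite(records$p_ec50)) || !all(is.finite(records$p_loec))) {
    stop_duotox("p_ec50 and p_loec must be finite", class = "duotox_integrity_error")
  }
  if (!is.null(records$split) &&
      !all(records$split %in% c("train", "test"))) {
    stop_duotox("split must be 'train' or 'test'", class = "duotox_integrity_error")
  }
  if (is.null(records$composite)) records$composite <- NA_real_
  if (is.null(records$flag)) records$flag <- ""
  records$flag[is.na(records$flag)] <- ""
  if (!is.null(molecules)) {
    extra <- setdiff(names(molecules), records$compound_id)
    if (length(extra)) {
      stop_duotox("molecules without matching record: ", paste(extra, collapse = ", "),
                  class = "duotox_integrity_error")
    }
  }
  structure(
    list(records = records, molecules = molecules, provenance = provenance),
    class = "toxicity_dataset"
  )
}

#' @export
print.toxicity_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<toxicity_dataset> %d compounds (%d train / %d test)\n",
              nrow(r), sum(r$split == "train"), sum(r$split == "test")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Load the packaged 50-compound quinolone toxicity table
#'
#' Returns the quinolone/fluoroquinolone dataset shipped with the package:
#' 50 compounds with green-algae toxicity (pEC50), bacterial genotoxicity
#' (pLOEC), the printed double-activity composite value, and the realized
#' 40-train / 10-test split. Row `2-C2H3-9-Cl-NAD` carries the printed
#' composite but is flagged `"inconsistent"`: the compositing arithmetic
#' applied to its endpoints gives +0.20, not the printed -0.17.
#'
#' @return a [toxicity_dataset] with 50 records; the printed composite is in
#'   column `composite_printed` and `composite` is left `NA` until computed
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "quinolone_toxicity.csv", package = "duotox")
  if (!nzchar(path) || !file.exists(path)) {
    stop_duotox("packaged fixture not found", class = "duotox_integrity_error")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("compound_id", "name", "p_ec50", "p_loec", "composite_printed",
            "split", "flag")
  if (!identical(names(d), need)) {
    stop_duotox("fixture is corrupted: unexpected columns", class = "duotox_integrity_error")
  }
  for (col in c("p_ec50", "p_loec", "composite_printed")) {
    d[[col]] <- as.numeric(normalize_minus(d[[col]]))
  }
  ok <- nrow(d) == 50L &&
    sum(d$split == "test") == 10L &&
    sum(d$split == "train") == 40L &&
    all(is.finite(d$p_ec50)) && all(is.finite(d$p_loec)) &&
    !anyDuplicated(d$compound_id)
  if (!ok) {
    stop_duotox("fixture is corrupted: integrity check failed",
                class = "duotox_integrity_error")
  }
  toxicity_dataset(d, provenance = "packaged quinolone double-activity table (n=50)")
}

#' Write a toxicity table to CSV
#'
#' Inverse of the fixture reader: writing and re-reading reproduces all
#' records at printed precision.
#'
#' @param dataset a [toxicity_dataset]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_toxicity_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "toxicity_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a toxicity table from CSV
#'
#' @param path CSV with at least `compound_id`, `name`, `p_ec50`, `p_loec`
#' @return a [toxicity_dataset]
#' @export
read_toxicity_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("p_ec50", "p_loec", "composite", "composite_printed"),
                        names(d))) {
    if (is.character(d[[col]])) d[[col]] <- as.numeric(normalize_minus(d[[col]]))
  }
  toxicity_dataset(d, provenance = path)
}

#' Re-randomize the train/test split
#'
#' The packaged fixture stores the realized split; this helper draws a fresh
#' seeded partition of the same sizes for sensitivity experiments.
#'
#' @param dataset a [toxicity_dataset]
#' @param n_train number of training compounds
#' @param seed integer seed
#' @return the dataset with a new `split` column
#' @export
resplit_dataset <- function(dataset, n_train = 40L, seed = 1L) {
  stopifnot(inherits(dataset, "toxicity_dataset"))
  n <- nrow(dataset$records)
  stopifnot(n_train >= 1L, n_train < n)
  withr_seed <- split_seed(seed, 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  idx <- sample.int(n, n_train)
  dataset$records$split <- "test"
  dataset$records$split[idx] <- "train"
  dataset
}

# closed set of externally computed properties the screening arithmetic consumes
PROPERTY_NAMES <- c("frequency", "total_energy", "log_kow", "t_half_river",
                    "dock_total_score", "dock_binding_energy")

#' Read an external property table
#'
#' Properties the pipeline consumes but never computes: DFT frequencies and
#' total energies, logKow, river half-life, docking total scores and binding
#' energies. The property set is closed; unknown names are rejected.
#'
#' @param path CSV with columns `compound_id`, `property_name`, `value` and
#'   optional `context` (e.g. a target PDB id)
#' @return data.frame of typed property records
#' @export
read_property_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "property_name", "value") %in% names(d))) {
    stop_duotox("property table needs compound_id, property_name, value columns",
                class = "duotox_schema_error")
  }
  if (is.character(d$value)) d$value <- as.numeric(normalize_minus(d$value))
  bad <- setdiff(unique(d$property_name), PROPERTY_NAMES)
  if (length(bad)) {
    stop_duotox("unknown property name(s): ", paste(bad, collapse = ", "),
                class = "duotox_schema_error")
  }
  if (!all(is.finite(d$value))) {
    stop_duotox("property values must be finite", class = "duotox_schema_error")
  }
  if (is.null(d$context)) d$context <- ""
  d[, c("compound_id", "property_name", "value", "context")]
}
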