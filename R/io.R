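#' Read a protein-groups table
#'
#' Parses a tab-separated search-engine protein table (one row per protein
#' group). Intensity columns are discovered by a configurable column-name
#' prefix (default `"iBAQ "`), so dialect drift between search engines is a
#' configuration change rather than a code change. Intensities of 0 and empty
#' cells are both read as missing: search-engine outputs write 0 for
#' non-detection, and treating 0 as an observed value would corrupt
#' half-minimum imputation.
#'
#' @param path path to a TSV file with a header line. Mandatory columns:
#'   `Protein IDs`, `Gene names`, `Reverse`, `Potential contaminant`, and at
#'   least one column starting with `intensity_prefix`.
#' @param intensity_prefix prefix identifying intensity columns; the sample
#'   name is the remainder of the column name.
#' @return a list of protein records; each record has `protein_group_id`,
#'   `gene_name`, `intensities` (named numeric, missing values absent as `NA`),
#'   `is_reverse`, `is_contaminant`.
#' @export
read_protein_groups <- function(path, intensity_prefix = "iBAQ ") {
  tab <- read_tsv_table(path)
  require_columns(tab, c("Protein IDs", "Gene names", "Reverse",
                         "Potential contaminant"), path)
  int_cols <- grep(paste0("^", escape_regex(intensity_prefix)), names(tab),
                   value = TRUE)
  if (length(int_cols) == 0L)
    stop("no intensity columns with prefix '", intensity_prefix, "' in ", path)
  ids <- as.character(tab[["Protein IDs"]])
  if (anyDuplicated(ids))
    stop("duplicate protein group ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)
  lapply(seq_len(nrow(tab)), function(i) {
    v <- vapply(int_cols, function(cl) parse_intensity(tab[[cl]][i]),
                numeric(1))
    names(v) <- samples
    list(protein_group_id = ids[i],
         gene_name = as.character(tab[["Gene names"]][i]),
         intensities = v,
         is_reverse = flag_set(tab[["Reverse"]][i]),
         is_contaminant = flag_set(tab[["Potential contaminant"]][i]))
  })
}

#' Read a phosphorylation-site table
#'
#' Parses a tab-separated p-site table. A site id is synthesised as
#' `GENE_RESPOS` (e.g. `"RRM2_T33"`) from the gene name, residue letter and
#' 1-based protein position, so sites join directly against annotation files.
#' Localisation probabilities are carried through but never used as an a
#' priori filter.
#'
#' @param path TSV path. Mandatory columns: `Gene names`, `Amino acid`,
#'   `Position`, `Localization prob`, `Reverse`, `Potential contaminant` and
#'   intensity columns.
#' @param intensity_prefix prefix of intensity columns (default
#'   `"Intensity "`).
#' @return list of site records with fields `site_id`, `gene_name`, `residue`,
#'   `position`, `localization_probability`, `intensities`, `is_reverse`,
#'   `is_contaminant`.
#' @export
read_phospho_sites <- function(path, intensity_prefix = "Intensity ") {
  tab <- read_tsv_table(path)
  require_columns(tab, c("Gene names", "Amino acid", "Position",
                         "Localization prob", "Reverse",
                         "Potential contaminant"), path)
  int_cols <- grep(paste0("^", escape_regex(intensity_prefix)), names(tab),
                   value = TRUE)
  if (length(int_cols) == 0L)
    stop("no intensity columns with prefix '", intensity_prefix, "' in ", path)
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)
  residues <- as.character(tab[["Amino acid"]])
  if (!all(residues %in% c("S", "T", "Y")))
    stop("column 'Amino acid' must be one of S, T, Y")
  pos <- as.integer(tab[["Position"]])
  if (any(is.na(pos)) || any(pos < 1L))
    stop("column 'Position' must hold 1-based integer positions")
  prob <- as.numeric(tab[["Localization prob"]])
  if (any(is.na(prob)) || any(prob < 0) || any(prob > 1))
    stop("column 'Localization prob' must lie in [0, 1]")
  site_ids <- paste0(tab[["Gene names"]], "_", residues, pos)
  if (anyDuplicated(site_ids))
    stop("duplicate site ids in ", path, ": ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    v <- vapply(int_cols, function(cl) parse_intensity(tab[[cl]][i]),
                numeric(1))
    names(v) <- samples
    list(site_id = site_ids[i],
         gene_name = as.character(tab[["Gene names"]][i]),
         residue = residues[i],
         position = pos[i],
         localization_probability = prob[i],
         intensities = v,
         is_reverse = flag_set(tab[["Reverse"]][i]),
         is_contaminant = flag_set(tab[["Potential contaminant"]][i]))
  })
}

#' Read a long-format drug-screen table
#'
#' One row per well: drug, cell line, dose in micromolar (0 for vehicle),
#' replicate number, raw signal (luminescence-like) and the well role.
#'
#' @param path CSV path with columns `drug`, `cell_line`, `dose_uM`,
#'   `replicate`, `signal`, `well_role`.
#' @return a data.frame of well records (one row per well).
#' @export
read_drug_screen <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  require_columns(tab, c("drug", "cell_line", "dose_uM", "replicate",
                         "signal", "well_role"), path)
  tab$dose_uM <- as.numeric(tab$dose_uM)
  if (any(is.na(tab$dose_uM)) || any(tab$dose_uM < 0))
    stop("column 'dose_uM' must be numeric and >= 0")
  tab$replicate <- as.integer(tab$replicate)
  if (any(is.na(tab$replicate)) || any(tab$replicate < 1L))
    stop("column 'replicate' must be an integer >= 1")
  roles <- c("sample", "positive_control", "negative_control")
  if (!all(tab$well_role %in% roles))
    stop("column 'well_role' must be one of: ", paste(roles, collapse = ", "))
  tab$signal <- as.numeric(tab$signal)
  tab
}

#' Read the annotation set
#'
#' Four two-column TSV files define the kinase universe, activation-loop
#' sites, kinase-substrate relationships and periodic-protein clusters.
#'
#' @param kinase_path TSV `kinase_id <tab> druggable` (logical flag).
#' @param loop_path TSV `kinase_id <tab> site_id` (activation-loop sites).
#' @param substrate_path TSV `kinase_id <tab> site_id` (substrate sites).
#' @param cluster_path TSV `cluster <tab> protein_id`, cluster labels 1..5.
#' @return an object of class `annotation_set` with elements `kinase_ids`,
#'   `druggable_kinases`, `activation_loop_sites`, `substrate_sites`
#'   (kinase-named lists of site-id vectors) and `periodic_clusters`
#'   (named list `"1"`..`"5"` of protein-id vectors).
#' @export
read_annotations <- function(kinase_path, loop_path, substrate_path,
                             cluster_path) {
  kin <- read_tsv_table(kinase_path)
  require_columns(kin, c("kinase_id", "druggable"), kinase_path)
  loops <- read_pair_map(loop_path, "kinase_id", "site_id")
  subs <- read_pair_map(substrate_path, "kinase_id", "site_id")
  cl <- read_tsv_table(cluster_path)
  require_columns(cl, c("cluster", "protein_id"), cluster_path)
  cl$cluster <- as.integer(cl$cluster)
  if (any(is.na(cl$cluster)) || any(!cl$cluster %in% 1:5))
    stop("cluster labels must be integers in 1..5")
  if (anyDuplicated(cl$protein_id))
    stop("periodic clusters must be disjoint; duplicated protein ids: ",
         paste(unique(cl$protein_id[duplicated(cl$protein_id)]),
               collapse = ", "))
  clusters <- split(cl$protein_id, factor(cl$cluster, levels = 1:5))
  annotation_set(
    kinase_ids = as.character(kin$kinase_id),
    druggable_kinases = as.character(
      kin$kinase_id[parse_logical(kin$druggable)]),
    activation_loop_sites = loops,
    substrate_sites = subs,
    periodic_clusters = clusters)
}

#' Construct an annotation set
#'
#' @param kinase_ids character vector of kinase identifiers.
#' @param druggable_kinases subset of `kinase_ids` that are drug targets.
#' @param activation_loop_sites named list (kinase -> character vector of
#'   site ids).
#' @param substrate_sites named list (kinase -> character vector of site ids).
#' @param periodic_clusters named list (`"1"`..`"5"` -> protein id vectors);
#'   clusters must be disjoint.
#' @return an `annotation_set` object.
#' @export
annotation_set <- function(kinase_ids, druggable_kinases = character(),
                           activation_loop_sites = list(),
                           substrate_sites = list(),
                           periodic_clusters = list()) {
  kinase_ids <- unique(as.character(kinase_ids))
  if (!all(druggable_kinases %in% kinase_ids))
    stop("druggable kinases must be a subset of kinase_ids")
  all_members <- unlist(periodic_clusters, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("periodic clusters must be disjoint")
  structure(list(kinase_ids = kinase_ids,
                 druggable_kinases = as.character(druggable_kinases),
                 activation_loop_sites = activation_loop_sites,
                 substrate_sites = substrate_sites,
                 periodic_clusters = periodic_clusters),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(paste0("annotation_set: %d kinases (%d druggable), ",
                     "%d with loop sites, %d with substrates, ",
                     "%d periodic clusters (%d proteins)\n"),
              length(x$kinase_ids), length(x$druggable_kinases),
              length(x$activation_loop_sites), length(x$substrate_sites),
              length(x$periodic_clusters),
              length(unlist(x$periodic_clusters))))
  invisible(x)
}

#' Write / read an abundance matrix as TSV
#'
#' The writer emits a `# scale: <tag>` schema comment followed by a header
#' line (`feature_id` then sample ids) and one row per feature. Values are
#' written with 15 significant digits so a write/read round trip reproduces
#' them to at least 12 significant digits. Missing cells are empty fields.
#'
#' @param x an `abundance_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# scale: ", x$scale), con)
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  vals <- x$values
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    cells <- ifelse(is.na(row), "", sprintf("%.15g", row))
    writeLines(paste(c(rownames(vals)[i], cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- "linear"
  if (startsWith(first, "# scale:"))
    scale <- trimws(sub("^# scale:", "", first))
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  abundance_matrix(m, scale = scale)
}

#' Write tables in the dialects the readers consume
#'
#' `write_protein_groups` / `write_phospho_sites` serialise a linear-scale
#' `abundance_matrix` as a search-engine-style TSV (intensity columns under
#' the configured prefix; missing cells written as 0, the non-detection
#' convention of those tables). `write_drug_screen` writes the long-format
#' well CSV. `write_annotations` writes the four two-column annotation TSVs
#' into a directory. All writers emit a `#` schema comment line and use 15
#' significant digits, so write/read round trips reproduce values to at
#' least 12 significant digits.
#'
#' @param x a linear-scale `abundance_matrix` (protein or p-site rows).
#' @param path output file path.
#' @param intensity_prefix intensity column prefix used on write.
#' @return `path` (or the directory for `write_annotations`), invisibly.
#' @export
write_protein_groups <- function(x, path, intensity_prefix = "iBAQ ") {
  stopifnot(inherits(x, "abundance_matrix"), x$scale == "linear")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema: protein_groups v1", con)
  header <- c("Protein IDs", "Gene names",
              paste0(intensity_prefix, colnames(x$values)),
              "Reverse", "Potential contaminant")
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(x$values))) {
    row <- x$values[i, ]
    cells <- ifelse(is.na(row), "0", sprintf("%.15g", row))
    writeLines(paste(c(rownames(x$values)[i], rownames(x$values)[i],
                       cells, "", ""), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_protein_groups
#' @export
write_phospho_sites <- function(x, path, intensity_prefix = "Intensity ") {
  stopifnot(inherits(x, "abundance_matrix"), x$scale == "linear")
  ids <- rownames(x$values)
  m <- regmatches(ids, regexec("^(.*)_([STY])([0-9]+)$", ids))
  if (any(lengths(m) != 4L))
    stop("rownames must be GENE_RESPOS site ids")
  gene <- vapply(m, `[[`, character(1), 2L)
  res <- vapply(m, `[[`, character(1), 3L)
  pos <- vapply(m, `[[`, character(1), 4L)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema: phospho_sites v1", con)
  header <- c("Gene names", "Amino acid", "Position", "Localization prob",
              paste0(intensity_prefix, colnames(x$values)),
              "Reverse", "Potential contaminant")
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(x$values))) {
    row <- x$values[i, ]
    cells <- ifelse(is.na(row), "0", sprintf("%.15g", row))
    writeLines(paste(c(gene[i], res[i], pos[i], "1",
                       cells, "", ""), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_protein_groups
#' @param wells a drug-screen data.frame (see [read_drug_screen()]).
#' @export
write_drug_screen <- function(wells, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema: drug_screen v1", con)
  writeLines("drug,cell_line,dose_uM,replicate,signal,well_role", con)
  writeLines(sprintf("%s,%s,%.15g,%d,%.15g,%s",
                     wells$drug, wells$cell_line, wells$dose_uM,
                     wells$replicate, wells$signal, wells$well_role), con)
  invisible(path)
}

#' @rdname write_protein_groups
#' @param annotations an `annotation_set`.
#' @param dir output directory (created if absent); files `kinases.tsv`,
#'   `activation_loops.tsv`, `substrates.tsv`, `periodic_clusters.tsv`.
#' @export
write_annotations <- function(annotations, dir) {
  stopifnot(inherits(annotations, "annotation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs <- function(df, header, file) {
    con <- file(file.path(dir, file), "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# schema: ", sub("[.]tsv$", "", file), " v1"), con)
    writeLines(paste(header, collapse = "\t"), con)
    if (nrow(df)) writeLines(paste(df[[1L]], df[[2L]], sep = "\t"), con)
  }
  write_pairs(data.frame(k = annotations$kinase_ids,
                         d = annotations$kinase_ids %in%
                           annotations$druggable_kinases),
              c("kinase_id", "druggable"), "kinases.tsv")
  unroll <- function(map) {
    data.frame(k = rep(names(map), lengths(map)),
               s = unlist(map, use.names = FALSE))
  }
  write_pairs(unroll(annotations$activation_loop_sites),
              c("kinase_id", "site_id"), "activation_loops.tsv")
  write_pairs(unroll(annotations$substrate_sites),
              c("kinase_id", "site_id"), "substrates.tsv")
  write_pairs(unroll(annotations$periodic_clusters),
              c("cluster", "protein_id"), "periodic_clusters.tsv")
  invisible(dir)
}

## internal parsing helpers ---------------------------------------------------

read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# empty cell or 0 -> NA (non-detection); otherwise must be a finite value >= 0
parse_intensity <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_real_)
  v <- suppressWarnings(as.numeric(cell))
  if (is.na(v)) stop("non-numeric intensity value: '", cell, "'")
  if (v < 0) stop("negative intensity value: ", v)
  if (v == 0) NA_real_ else v
}

flag_set <- function(cell) {
  !is.na(cell) & trimws(as.character(cell)) == "+"
}

parse_logical <- function(x) {
  v <- toupper(trimws(as.character(x)))
  out <- v %in% c("TRUE", "T", "YES", "1")
  bad <- !out & !v %in% c("FALSE", "F", "NO", "0")
  if (any(bad)) stop("cannot parse logical value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

read_pair_map <- function(path, key_col, value_col) {
  tab <- read_tsv_table(path)
  require_columns(tab, c(key_col, value_col), path)
  if (nrow(tab) == 0L) return(list())
  lapply(split(as.character(tab[[value_col]]),
               as.character(tab[[key_col]])), unique)
}

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
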