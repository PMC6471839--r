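# Readers and writers for the package's plain-text formats.
#
# Database FASTA header grammar (one record per protein):
#   >ACC|GN=<gene or ->|UR=<uniref id or ->|TX=<family;genus;species;strain>|DECOY=<0/1>|HOST=<0/1>
# PSM TSV columns: spectrum_id, subject_id, peptide, accessions
# (semicolon-joined), score.  All TSVs: header row, UTF-8, tab separator,
# no quoting; tabs are forbidden inside fields.

#' Tag a count matrix with its measurement method
#'
#' @param mat numeric matrix, features x subjects, non-negative.
#' @param method "proteomics" or "16S".
#' @return the matrix with class \code{abundance_matrix} and a
#'   \code{method} attribute.
#' @export
abundance_matrix <- function(mat, method = c("proteomics", "16S")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(mat < 0)) stopf("abundance matrix must be non-negative")
  structure(mat, method = method,
            class = c("abundance_matrix", class(mat)))
}

fasta_header <- function(db) {
  sprintf(">%s|GN=%s|UR=%s|TX=%s|DECOY=%d|HOST=%d",
          db$accession,
          ifelse(nzchar(db$gene_name), db$gene_name, "-"),
          ifelse(nzchar(db$uniref50_id), db$uniref50_id, "-"),
          paste(db$family, db$genus, db$species, db$strain, sep = ";"),
          as.integer(db$is_decoy), as.integer(db$is_host))
}

#' Write a protein database to FASTA
#'
#' @param database \code{protein_db} data.frame.
#' @param path output file.
#' @param width sequence line width.
#' @export
write_database <- function(database, path, width = 60L) {
  headers <- fasta_header(database)
  con <- file(path, open = "wb")  # "wb": byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(database))) {
    s <- database$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(headers[i], substring(s, starts,
                                       pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' Sequences are parsed with Biostrings; headers must follow the
#' package's structured grammar.  Malformed headers are reported with
#' their line number; duplicate accessions are an error.
#'
#' @param path FASTA file.
#' @param quiet suppress the record-count message.
#' @return \code{protein_db} data.frame.
#' @export
read_database <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  lines <- readLines(path)
  header_lines <- which(startsWith(lines, ">"))
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  parse_fail <- function(i, why) {
    stopf("malformed FASTA header at line %d (%s): >%s",
          header_lines[i], why, headers[i])
  }
  if (length(bad)) parse_fail(bad[1], "expected 6 |-separated fields")
  field <- function(k) vapply(parts, `[[`, character(1), k)
  need <- c("GN=", "UR=", "TX=", "DECOY=", "HOST=")
  for (k in 2:6) {
    pre <- need[k - 1L]
    badk <- which(!startsWith(field(k), pre))
    if (length(badk)) parse_fail(badk[1], sprintf("missing %s field", pre))
  }
  strip <- function(k) sub("^[A-Z]+=", "", field(k))
  tx <- strsplit(strip(4), ";", fixed = TRUE)
  badtx <- which(lengths(tx) != 4L)
  if (length(badtx))
    parse_fail(badtx[1], "TX field needs family;genus;species;strain")
  acc <- field(1)
  dup <- acc[duplicated(acc)]
  if (length(dup))
    stopf("duplicate accession(s) in database: %s",
          paste(unique(dup), collapse = ", "))
  blank_if_dash <- function(x) ifelse(x == "-", "", x)
  db <- data.frame(
    accession = acc,
    sequence = as.character(seqs),
    gene_name = blank_if_dash(strip(2)),
    uniref50_id = blank_if_dash(strip(3)),
    family = vapply(tx, `[[`, character(1), 1),
    genus = vapply(tx, `[[`, character(1), 2),
    species = vapply(tx, `[[`, character(1), 3),
    strain = vapply(tx, `[[`, character(1), 4),
    is_decoy = strip(5) == "1",
    is_host = strip(6) == "1",
    stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("protein_db", "data.frame")
  if (!quiet)
    message(sprintf(
      "loaded %d records: %d targets (%d host), %d decoys",
      nrow(db), sum(!db$is_decoy), sum(db$is_host & !db$is_decoy),
      sum(db$is_decoy)))
  db
}

check_no_tabs <- function(df) {
  chr <- vapply(df, is.character, logical(1))
  if (any(vapply(df[chr], function(x) any(grepl("\t", x, fixed = TRUE)),
                 logical(1))))
    stopf("tab characters are forbidden inside TSV fields")
  invisible(df)
}

write_tsv <- function(df, path) {
  check_no_tabs(df)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "")
  invisible(path)
}

#' Write PSMs to TSV
#' @param psms PSM data.frame.
#' @param path output file.
#' @export
write_psms <- function(psms, path) {
  write_tsv(psms[, c("spectrum_id", "subject_id", "peptide", "accessions",
                     "score")], path)
}

#' Read PSMs from TSV
#'
#' Bracketed modification tags in the peptide column (e.g.
#' \code{"PEPT[+0.98]IDER"}) are stripped to the bare sequence; counting
#' throughout the pipeline is per peptide sequence.  When a database is
#' supplied, every matched accession must resolve against it.
#'
#' @param path TSV with columns spectrum_id, subject_id, peptide,
#'   accessions, score.
#' @param database optional \code{protein_db} to validate accessions.
#' @return PSM data.frame, row order preserved.
#' @export
read_psms <- function(path, database = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(spectrum_id = "character",
                                         subject_id = "character",
                                         peptide = "character",
                                         accessions = "character"))
  need <- c("spectrum_id", "subject_id", "peptide", "accessions", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("PSM table %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  df <- df[, need]
  df$peptide <- toupper(gsub("\\[[^]]*\\]", "", df$peptide))
  if (any(!nzchar(df$peptide)))
    stopf("empty peptide sequence in %s", path)
  if (!is.null(database)) {
    accs <- unique(unlist(strsplit(df$accessions, ";", fixed = TRUE)))
    bad <- setdiff(accs, database$accession)
    if (length(bad))
      stopf("PSM accessions not in database: %s",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  df
}

#' Write a feature-by-subject matrix as TSV
#' @param mat matrix with row and column names.
#' @param path output file.
#' @param feature_col name of the leading feature-id column.
#' @export
write_matrix_tsv <- function(mat, path, feature_col = "feature") {
  df <- data.frame(rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write_tsv(df, path)
}

#' Read a feature-by-subject matrix from TSV
#' @param path TSV whose first column holds feature ids.
#' @param method optional method tag; when given, the result is an
#'   \code{\link{abundance_matrix}}.
#' @export
read_matrix_tsv <- function(path, method = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  if (!is.null(method)) mat <- abundance_matrix(mat, method)
  mat
}

#' Read a gene-to-pathway annotation table
#' @param path TSV with columns pathway_id, gene_name.
#' @return data.frame with those two columns.
#' @export
read_pathway_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pathway_id", "gene_name")
  if (!all(need %in% names(df)))
    stopf("pathway table %s needs columns: %s", path,
          paste(need, collapse = ", "))
  if (nrow(df) == 0L) stopf("pathway table %s is empty", path)
  df[, need]
}

#' Write the full report bundle of a pipeline run
#'
#' Emits the accounting table (source x annotation strata with spectral
#' counts, unique peptide sequences and metacluster counts), the strain
#' detection tier table, rank profiles, the metacluster count matrix,
#' correlation tables, pathway contrast tables and a run manifest with a
#' config hash — all as TSV/JSON under \code{outdir}.
#'
#' @param results pipeline results list (see \code{\link{run_pipeline}}).
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_reports <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stopf("outdir %s is not writable", outdir)
  paths <- character(0)
  emit <- function(df, name, feature_col = NULL) {
    p <- file.path(outdir, name)
    if (is.matrix(df)) write_matrix_tsv(df, p, feature_col %||% "feature")
    else write_tsv(df, p)
    paths <<- c(paths, p)
  }
  emit(results$accounting, "accounting.tsv")
  if (!is.null(results$tiers))
    emit(results$tiers, "strain_tiers.tsv", "tier")
  for (r in names(results$profiles %||% list()))
    emit(results$profiles[[r]]$spectra, sprintf("profile_%s.tsv", r), r)
  if (!is.null(results$metacluster_counts))
    emit(unclass(results$metacluster_counts), "metacluster_counts.tsv",
         "metacluster_id")
  if (!is.null(results$correlations))
    emit(results$correlations, "correlations.tsv")
  if (!is.null(results$pairwise))
    emit(results$pairwise, "pairwise_metacluster_correlations.tsv")
  if (!is.null(results$pathway_contrasts)) {
    emit(results$pathway_contrasts$per_member, "pathway_members.tsv")
    emit(results$pathway_contrasts$verdicts, "pathway_verdicts.tsv")
  }
  if (!is.null(results$fdr)) {
    emit(data.frame(score_threshold = results$fdr$score_threshold,
                    n_target = results$fdr$n_target,
                    n_decoy = results$fdr$n_decoy,
                    fdr = results$fdr$fdr), "fdr_report.tsv")
  }
  manifest <- list(
    package = "metapep",
    version = as.character(utils::packageVersion("metapep")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = results$spec$seed %||% NA,
    config_hash = config_hash(results$spec),
    files = basename(paths))
  if (!is.null(results$protein_level_fdr))
    manifest$protein_level_fdr <- results$protein_level_fdr
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(outdir, "manifest.json")))
}

# md5 of the canonical JSON rendering of a config object
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
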