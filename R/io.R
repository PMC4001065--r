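# External representations: variant annotation TSV, PDB structures, YAML
# run configuration, ranked and enrichment output tables.

.NUMERIC_ANN_COLS <- c("protein_position", "ddg", "gamma", "bfactor_norm",
                       "rmsf_norm", "p_flexible", "rsa_percent", "rvis",
                       "composite_score", "maf_afr", "maf_eur",
                       "del_count", "cons_count", "flex_percentile")
.LOGICAL_ANN_COLS <- c("on_patch", "in_domain", "sc_residue",
                       "disulfide_involved")

#' Read a variant annotation table
#'
#' Reads a tab-separated annotation table with a header row into a
#' \linkS4class{VariantCohort}. Default column names are lowercase snake
#' case (\code{gene_symbol}, \code{protein_position}, \code{ref_aa},
#' \code{alt_aa}, \code{class_label}, plus any annotation columns); a
#' \code{dialect} mapping renames arbitrary headers, e.g.
#' \code{c(gene_symbol = "Gene", ref_aa = "AA1")}. Class labels are
#' normalized to lower case. Unparseable numeric cells become \code{NA}
#' and are logged with their row number; empty cells and \code{"NA"} are
#' missing values. No data row is ever silently dropped; duplicated
#' (gene, position, ref, alt) rows raise a warning but both are kept.
#'
#' @param path file path of the TSV.
#' @param dialect named character vector mapping canonical column names to
#'   the file's headers.
#' @return a \linkS4class{VariantCohort}; reader messages are in
#'   \code{\link{cohortLog}}.
#' @export
readVariantTable <- function(path, dialect = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("", "NA"),
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  log <- character()
  if (length(dialect)) {
    for (canon in names(dialect)) {
      hit <- match(dialect[[canon]], colnames(raw))
      if (!is.na(hit)) colnames(raw)[hit] <- canon
    }
  }
  missing <- setdiff(.REQUIRED_VARIANT_COLS, colnames(raw))
  if (length(missing))
    stop("required column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  for (nm in intersect(.NUMERIC_ANN_COLS, colnames(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(!is.na(raw[[nm]]) & is.na(parsed))
    if (length(bad)) {
      msg <- sprintf("column %s: unparseable numeric cell(s) set to NA at row(s) %s",
                     nm, paste(bad, collapse = ","))
      warning(msg, call. = FALSE)
      log <- c(log, msg)
    }
    raw[[nm]] <- parsed
  }
  for (nm in intersect(.LOGICAL_ANN_COLS, colnames(raw))) {
    x <- tolower(raw[[nm]])
    raw[[nm]] <- ifelse(is.na(x), NA,
                        x %in% c("true", "yes", "1", "t"))
  }
  key <- with(raw, paste(gene_symbol, protein_position, ref_aa, alt_aa))
  if (anyDuplicated(key)) {
    msg <- sprintf("duplicate variant row(s): %s (all kept)",
                   paste(unique(key[duplicated(key)]), collapse = "; "))
    warning(msg, call. = FALSE)
    log <- c(log, msg)
  }
  variantCohort(raw, log = log)
}

#' Write a variant annotation table
#'
#' Inverse of \code{\link{readVariantTable}}: tab-separated, header row,
#' missing values written as \code{NA}. Writing then reading reproduces
#' all non-missing values.
#'
#' @param cohort a \linkS4class{VariantCohort} (or data.frame).
#' @param path output file path.
#' @export
writeVariantTable <- function(cohort, path) {
  v <- if (is(cohort, "VariantCohort")) as.data.frame(variantData(cohort))
       else as.data.frame(cohort)
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of standard residues into a
#' \linkS4class{ProteinStructure}: HETATM records, waters and hydrogens
#' are ignored, only the first alternate location is kept, and multi-model
#' files contribute model 1 only. Residue numbering follows the source
#' file verbatim.
#'
#' @param path PDB file path.
#' @return a \linkS4class{ProteinStructure}.
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(.AA3), , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records of standard residues in ", path)
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  at <- at[!grepl("^H", at$elety), , drop = FALSE]
  # first altloc wins
  at <- at[!duplicated(at[, c("chain", "resno", "elety")]), , drop = FALSE]
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop("malformed coordinates in ", path, " (atom serial ",
         paste(at$eleno[bad], collapse = ","), ")")
  elesy <- at$elesy
  guess <- is.na(elesy) | elesy == ""
  elesy[guess] <- substr(gsub("[0-9]", "", at$elety[guess]), 1L, 1L)
  proteinStructure(
    data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
               resno = at$resno, resid = at$resid, elety = at$elety,
               elesy = elesy, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    source = path)
}

#' Write a ProteinStructure as PDB ATOM records
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @export
writeStructure <- function(structure, path) {
  a <- atomRecords(structure)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$elety) < 4L, paste0(" ", substr(paste0(a$elety, "  "), 1L, 3L)), a$elety),
    a$resid, a$chain, a$resno, a$x, a$y, a$z, a$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the ranked variant table
#'
#' Tab-separated output sorted by descending score, ties broken by gene
#' symbol then protein position; one column per feature flag plus
#' \code{sds}, \code{priority}, \code{tolerance_class}, \code{excluded}
#' and \code{final_priority}. Byte output is deterministic for a fixed
#' input.
#'
#' @param results an \linkS4class{SdsResults}.
#' @param path output file path.
#' @export
writeRankedTable <- function(results, path) {
  tb <- as.data.frame(sdsTable(results))
  ord <- order(-tb$sds, tb$gene_symbol, tb$protein_position,
               method = "radix")
  utils::write.table(tb[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the enrichment result table
#'
#' @param enrichment data.frame from \code{\link{featureEnrichment}}.
#' @param path output file path.
#' @export
writeEnrichmentTable <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a YAML run configuration
#'
#' The configuration may hold a \code{thresholds} block (see
#' \code{\link{thresholdConfigFromList}}), a \code{dialect} block of
#' column-name mappings, and free-form path entries.
#'
#' @param path YAML file path.
#' @return list with elements \code{thresholds}
#'   (\linkS4class{ThresholdConfig}), \code{dialect} (named character
#'   vector) and \code{raw} (the full parsed list).
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  thresholds <- if (!is.null(raw$thresholds))
    thresholdConfigFromList(raw$thresholds) else thresholdConfig()
  dialect <- if (!is.null(raw$dialect)) unlist(raw$dialect) else character()
  list(thresholds = thresholds, dialect = dialect, raw = raw)
}
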