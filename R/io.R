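## Readers and writers for the pipeline's file formats.  FASTA goes
## through Biostrings and GMT reading through fgsea; MGF, SIF and
## two-column peak lists are simple line formats written/parsed here.

#' Write / read a protein FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write / read a GMT pathway file
#'
#' Tab-delimited: pathway id, description, then member accessions.
#'
#' @param pathways named list of member vectors.
#' @param path file path.
#' @param descriptions optional per-pathway description strings.
#' @return `read_gmt` returns a named list of member vectors.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read an interaction edge list (SIF-style two-column TSV)
#'
#' @param edges data frame with columns `from`, `to`.
#' @param path file path.
#' @return `read_sif` returns a data frame `from`, `to`.
#' @export
write_sif <- function(edges, path) {
  write.table(edges[, c("from", "to")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  e <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("from", "to"),
                  stringsAsFactors = FALSE)
  e
}

#' Write / read peak lists as MGF
#'
#' Minimal Mascot generic format: one `BEGIN IONS` block per peak list
#' with a `TITLE=` carrying the list id and `m/z intensity` lines.
#'
#' @param peak_lists named list of data frames (`mz`, `intensity`).
#' @param path file path.
#' @return `read_mgf` returns a named list of data frames.
#' @export
write_mgf <- function(peak_lists, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(peak_lists)) {
    pl <- peak_lists[[id]]
    writeLines(c("BEGIN IONS", paste0("TITLE=", id),
                 sprintf("%.6f %.4f", pl$mz, pl$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list(); cur <- NULL; id <- NULL
  for (l in lines) {
    if (l == "BEGIN IONS") { cur <- character(); id <- NULL }
    else if (l == "END IONS") {
      m <- do.call(rbind, strsplit(cur, "\\s+"))
      pl <- if (is.null(m)) data.frame(mz = numeric(),
                                       intensity = numeric())
            else data.frame(mz = as.numeric(m[, 1]),
                            intensity = as.numeric(m[, 2]))
      out[[if (is.null(id)) as.character(length(out) + 1) else id]] <- pl
    } else if (startsWith(l, "TITLE=")) id <- sub("^TITLE=", "", l)
    else if (grepl("^[0-9]", l)) cur <- c(cur, l)
  }
  out
}

#' Read a two-column text peak list
#'
#' Whitespace- or comma-separated `m/z intensity` rows; comment lines
#' starting with `#` are skipped.
#'
#' @param path file path.
#' @return data frame `mz`, `intensity`, sorted by m/z.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, strsplit(trimws(lines), "[,[:space:]]+"))
  pl <- data.frame(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
  pl[order(pl$mz), , drop = FALSE]
}

#' Write / read a spot-volume CSV
#'
#' Header `spot_id,raw_A,raw_B[,accession]`.
#'
#' @param spots spot data frame (extra ground-truth columns are not
#'   written).
#' @param path file path.
#' @return `read_spot_csv` returns the data frame.
#' @export
write_spot_csv <- function(spots, path) {
  keep <- intersect(c("spot_id", "raw_A", "raw_B", "accession"),
                    names(spots))
  write.csv(spots[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a densitometry CSV
#'
#' Header `replicate,condition,target_density,loading_density`.
#'
#' @param dens densitometry data frame.
#' @param path file path.
#' @return `read_densitometry_csv` returns the data frame.
#' @export
write_densitometry_csv <- function(dens, path) {
  write.csv(dens, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_densitometry_csv
#' @export
read_densitometry_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write the planted ground truth as a JSON sidecar
#'
#' @param truth the `truth` element of [make_synthetic_study()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  # named atomic vectors become JSON objects so names survive round-trip
  tr <- lapply(truth, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write every synthetic input of a study to a directory
#'
#' Emits `proteins.fasta`, `spots.csv`, `peaks.mgf`, `pathways.gmt`,
#' `interactions.sif`, `densitometry.csv` and `truth.json`.
#'
#' @param study output of [make_synthetic_study()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "proteins.fasta"),
    spots = file.path(dir, "spots.csv"),
    mgf = file.path(dir, "peaks.mgf"),
    gmt = file.path(dir, "pathways.gmt"),
    sif = file.path(dir, "interactions.sif"),
    densitometry = file.path(dir, "densitometry.csv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(study$db, paths[["fasta"]])
  write_spot_csv(study$spots, paths[["spots"]])
  write_mgf(study$peaks$peak_lists, paths[["mgf"]])
  write_gmt(study$kb$pathways, paths[["gmt"]])
  write_sif(study$kb$edges, paths[["sif"]])
  write_densitometry_csv(study$densitometry, paths[["densitometry"]])
  write_truth_json(study$truth, paths[["truth"]])
  paths
}
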