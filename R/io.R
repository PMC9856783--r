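#' Read and write per-cycle reads as FASTA/FASTQ
#'
#' Reads are written one record per read (counts expanded), FASTQ with a
#' constant dummy quality of "I".  Reading aggregates identical
#' sequences into counts.  Gzip-compressed files are handled by the
#' underlying Biostrings readers/writers.
#'
#' @param reads a [CycleReads-class].
#' @param path output file.
#' @param format "fasta" or "fastq".
#' @return `writeCycleReads` returns `path` invisibly; `readCycleReads`
#'   returns a [CycleReads-class].
#' @export
writeCycleReads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is(reads, "CycleReads"))
  seqs <- rep(sequences(reads), counts(reads))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_read%06d", cycleLabel(reads), seq_along(x))
  if (format == "fastq") {
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' @param cycleLabel label for the returned object.
#' @rdname writeCycleReads
#' @export
readCycleReads <- function(path, cycleLabel, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  seqs <- as.character(x)
  tab <- rowsum(rep(1L, length(seqs)), seqs, reorder = FALSE)
  cycleReads(cycleLabel, rownames(tab), as.integer(tab[, 1L]))
}

#' Read and write frequency tables as TSV
#'
#' Columns: sequence, count, frequency.  The cycle label, retained-read
#' total and rejection tallies are stored in `#key=value` header lines
#' so the file round-trips.
#'
#' @param table a [FrequencyTable-class].
#' @param path TSV file path.
#' @return `writeFrequencyTable` returns `path` invisibly;
#'   `readFrequencyTable` a [FrequencyTable-class].
#' @export
writeFrequencyTable <- function(table, path) {
  stopifnot(is(table, "FrequencyTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#cycle_label=", table@cycleLabel),
    paste0("#total_reads=", table@totalReads),
    paste0("#rejections=", paste(names(table@rejections), table@rejections,
                                 sep = ":", collapse = ","))
  ), con)
  utils::write.table(
    data.frame(sequence = table@sequences, count = table@counts,
               frequency = table@frequencies),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeFrequencyTable
#' @export
readFrequencyTable <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- sub("^#[a-z_]+=", "", hdr)
  lab <- meta[1L]
  total <- as.integer(meta[2L])
  rej_kv <- strsplit(strsplit(meta[3L], ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  rej <- stats::setNames(
    vapply(rej_kv, function(x) as.integer(x[2L]), integer(1)),
    vapply(rej_kv, `[`, character(1), 1L)
  )
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 3L,
                         colClasses = c("character", "integer", "numeric"))
  new("FrequencyTable",
    cycleLabel = lab, sequences = d$sequence, counts = d$count,
    frequencies = d$count / total, totalReads = total, rejections = rej
  )
}

#' Read and write ddPCR droplet amplitudes as CSV
#'
#' One droplet per row, columns `well`, `amplitude`.
#'
#' @param droplets a [DropletSet-class] or list of them.
#' @param path CSV file path.
#' @return `writeDroplets` returns `path` invisibly; `readDroplets` a
#'   named list of [DropletSet-class], one per well.
#' @export
writeDroplets <- function(droplets, path) {
  if (is(droplets, "DropletSet")) droplets <- list(droplets)
  d <- do.call(rbind, lapply(droplets, function(x) {
    data.frame(well = x@wellId, amplitude = amplitudes(x))
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDroplets
#' @export
readDroplets <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "numeric"))
  lapply(split(d, d$well), function(w) dropletSet(w$well[1L], w$amplitude))
}

#' Read and write melt curves as long-format CSV
#'
#' Columns: aptamer_id, replicate, protein_conc_nM, temperature_C, rfu.
#'
#' @param curves list of [MeltCurve-class].
#' @param path CSV file path.
#' @return `writeMeltCurves` returns `path` invisibly; `readMeltCurves`
#'   a list of [MeltCurve-class], one per
#'   aptamer/replicate/concentration combination.
#' @export
writeMeltCurves <- function(curves, path) {
  if (is(curves, "MeltCurve")) curves <- list(curves)
  d <- do.call(rbind, lapply(curves, function(x) {
    data.frame(aptamer_id = x@aptamerId, replicate = x@replicateId,
               protein_conc_nM = x@proteinConcnM,
               temperature_C = x@temperature, rfu = x@rfu)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMeltCurves
#' @export
readMeltCurves <- function(path) {
  d <- utils::read.csv(path)
  key <- paste(d$aptamer_id, d$replicate, d$protein_conc_nM, sep = "\r")
  out <- lapply(split(d, key), function(w) {
    w <- w[order(w$temperature_C), , drop = FALSE]
    meltCurve(w$aptamer_id[1L], w$protein_conc_nM[1L], w$temperature_C,
              w$rfu, w$replicate[1L])
  })
  names(out) <- NULL
  out
}

#' Write clustered families as TSV
#'
#' Two files: the family table (family_id, seed, n_members, one
#' frequency column per cycle) and the member map (sequence, family_id).
#'
#' @param familySet a [FamilySet-class].
#' @param familiesPath,membersPath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeFamilies <- function(familySet, familiesPath, membersPath) {
  stopifnot(is(familySet, "FamilySet"))
  fam <- familySet@families
  if (ncol(familySet@cycleFrequencies)) {
    freq <- as.data.frame(familySet@cycleFrequencies)
    names(freq) <- paste0("freq_", colnames(familySet@cycleFrequencies))
    fam <- cbind(fam, freq)
  }
  utils::write.table(fam, familiesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(familySet@members, membersPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(familiesPath, membersPath))
}
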