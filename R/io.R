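#' Read a VCF file into site records
#'
#' Reads a VCF 4.2 file restricted to the DP:AD dialect: biallelic records
#' with FORMAT fields DP (total depth) and AD (ref,alt allele depths) for a
#' single sample. Multiallelic sites are skipped with a message.
#'
#' @param path VCF path (plain or gzipped).
#' @return A `site_records` data frame.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in ", path)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (!"AD" %in% fmt_keys) {
    stop("VCF ", path, " lacks the required FORMAT key AD")
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message("skipping ", sum(multi), " multiallelic site(s)")
  }
  keep <- !multi
  ad <- vcfR::extract.gt(v, "AD")[keep, 1]
  dp <- vcfR::extract.gt(v, "DP")[keep, 1]
  ad2 <- do.call(rbind, strsplit(ad, ","))
  alt_depth <- as.integer(ad2[, 2])
  depth <- if (all(is.na(dp))) {
    as.integer(ad2[, 1]) + alt_depth
  } else {
    as.integer(dp)
  }
  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    depth = depth, alt_depth = alt_depth,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_records", "data.frame")
  out
}

#' Write site records as minimal VCF 4.2
#'
#' One sample, FORMAT `DP:AD` with `AD = ref_depth,alt_depth`.
#'
#' @param records A `site_records` data frame.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, sample_name = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bafscreen",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  ), con)
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", ".", "DP:AD",
                paste0(records$depth, ":",
                       records$depth - records$alt_depth, ",",
                       records$alt_depth),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write site records as TSV
#' @param records A `site_records` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the simulator's site TSV
#' @param path TSV path with columns chrom, pos, ref, alt, depth, alt_depth.
#' @return A `site_records` data frame.
#' @export
read_site_tsv <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_depth")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  class(out) <- c("site_records", "data.frame")
  out
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors; sequences are written wrapped at 60 columns.
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @return `write_fasta`: invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Minimal 4-line-record FASTQ IO preserving read ids, sequences and quality
#' strings. Gzipped files are handled transparently (by extension on write,
#' by content on read).
#'
#' @param path FASTQ path.
#' @return `read_fastq`: data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ ", path, ": ", length(lines),
         " lines is not a multiple of 4")
  }
  i <- seq(1, length(lines), by = 4)
  if (!all(startsWith(lines[i], "@"))) {
    bad <- i[!startsWith(lines[i], "@")][1]
    stop("malformed FASTQ ", path, " at line ", bad, ": header must start with @")
  }
  data.frame(id = sub("^@", "", lines[i]),
             seq = lines[i + 1], qual = lines[i + 3],
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @return `write_fastq`: invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Read / write Newick trees
#'
#' Wrappers over ape; internal node labels carry bootstrap supports.
#'
#' @param path Newick path.
#' @return `read_newick`: an [ape::phylo].
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree An [ape::phylo].
#' @return `write_newick`: invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Write a PHYLIP square distance matrix
#'
#' dnadist-compatible output: taxon count on the first line, then one row
#' per taxon with the name padded to 10 characters.
#'
#' @param D A `distance_matrix` or plain matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip_dist <- function(D, path) {
  if (inherits(D, "distance_matrix")) D <- D$D
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    nm <- substr(sprintf("%-10s", rownames(D)[i]), 1, 10)
    writeLines(paste0(nm, paste(sprintf("%9.6f", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a study contamination-count table from TSV
#'
#' @param path TSV with columns `study`, `uncontaminated`, `contaminated`.
#' @return A `study_table`.
#' @export
read_study_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("study", "uncontaminated", "contaminated")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  study_table(tab$study, tab$uncontaminated, tab$contaminated)
}
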