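# Readers/writers for the plain-text formats the pipeline touches, plus
# input validation. The pipeline entry point is the long-form allele count
# table; upstream read processing (demultiplexing, alignment, deduplication)
# is out of scope, with only the UMI pattern rule kept as a validator.

COUNT_COLUMNS <- c("snp_id", "direction", "allele", "sample_id",
                   "condition", "replicate", "count")

validate_allele_counts <- function(tab) {
  missing <- setdiff(COUNT_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("allele count table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_dir <- which(!tab$direction %in% c("fwd", "rev"))
  if (length(bad_dir) > 0) {
    stop("row ", bad_dir[1], ": direction must be 'fwd' or 'rev', got '",
         tab$direction[bad_dir[1]], "'")
  }
  bad_allele <- which(!tab$allele %in% c("ref", "alt"))
  if (length(bad_allele) > 0) {
    stop("row ", bad_allele[1], ": allele must be 'ref' or 'alt'")
  }
  bad_cond <- which(!tab$condition %in% c("dna", "control", "caffeine"))
  if (length(bad_cond) > 0) {
    stop("row ", bad_cond[1], ": condition must be dna/control/caffeine")
  }
  if (!is.numeric(tab$count) || any(is.na(tab$count)) ||
      any(tab$count != floor(tab$count))) {
    bad <- which(is.na(tab$count) | tab$count != floor(tab$count))[1]
    stop("row ", bad, ": count must be a non-negative integer")
  }
  bad_count <- which(tab$count < 0)
  if (length(bad_count) > 0) {
    stop("row ", bad_count[1], ": negative count ", tab$count[bad_count[1]])
  }
  key <- paste(tab$snp_id, tab$direction, tab$allele, tab$sample_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("row ", dup[1], ": duplicate (snp_id, direction, allele, sample_id) key")
  }
  # every RNA (snp, direction) needs DNA rows for both alleles
  rna_pairs <- unique(paste(tab$snp_id, tab$direction, sep = "\r")[tab$condition != "dna"])
  dna <- tab[tab$condition == "dna", ]
  dna_key <- paste(dna$snp_id, dna$direction, sep = "\r")
  dna_ok <- intersect(unique(dna_key[dna$allele == "ref"]),
                      unique(dna_key[dna$allele == "alt"]))
  orphan <- setdiff(rna_pairs, dna_ok)
  if (length(orphan) > 0) {
    id <- strsplit(orphan[1], "\r", fixed = TRUE)[[1]]
    stop("RNA rows for SNP '", id[1], "' direction '", id[2],
         "' lack DNA rows for both alleles (every RNA pair must have DNA rows)")
  }
  invisible(tab)
}

#' Read a long-form allele count table
#'
#' The table is the pipeline's entry point: one row per
#' (snp_id, direction, allele, sample_id) with the sample's condition
#' (`dna`, `control`, or `caffeine`), replicate index, and read count.
#' Malformed input is rejected with an error naming the offending row;
#' every RNA (snp, direction) pair must have DNA rows for both alleles.
#'
#' @param path Path to a tab-separated file with header columns `snp_id`,
#'   `direction`, `allele`, `sample_id`, `condition`, `replicate`, `count`.
#' @return A validated tibble.
#' @seealso [write_allele_counts()]
#' @export
read_allele_counts <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  missing <- setdiff(COUNT_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("allele count file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  count_num <- suppressWarnings(as.numeric(tab$count))
  if (any(is.na(count_num))) {
    stop("row ", which(is.na(count_num))[1], ": count '",
         tab$count[which(is.na(count_num))[1]], "' is not an integer")
  }
  tab$count <- count_num
  tab$replicate <- suppressWarnings(as.integer(tab$replicate))
  if (any(is.na(tab$replicate))) {
    stop("row ", which(is.na(tab$replicate))[1], ": replicate is not an integer")
  }
  tab <- tibble::as_tibble(tab[, COUNT_COLUMNS])
  validate_allele_counts(tab)
  tab
}

#' Write an allele count table as TSV
#'
#' @param table Allele count table (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(table, path) {
  validate_allele_counts(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Validate unique molecular identifiers against an IUPAC pattern
#'
#' Reads carry a designed UMI whose positions follow a fixed IUPAC code
#' (default `RDHBVDHBVD`); UMIs that are shorter, longer, or mismatch any
#' position are rejected upstream of counting.
#'
#' @param umi Character vector of UMI sequences.
#' @param pattern IUPAC pattern; each character one of
#'   A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @return Logical vector: `TRUE` where the UMI matches the pattern exactly
#'   position by position (and has the pattern's length).
#' @examples
#' validate_umi("AAACAAACAA")  # TRUE
#' validate_umi("CAAAAAAAAA")  # FALSE: C not in R = {A, G}
#' @export
validate_umi <- function(umi, pattern = "RDHBVDHBVD") {
  codes <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("pattern contains non-IUPAC character(s): ", paste(bad, collapse = ", "))
  }
  L <- length(codes)
  ok <- nchar(umi) == L
  if (!any(ok)) return(ok)
  mat <- matrix("", nrow = sum(ok), ncol = L)
  chars <- strsplit(toupper(umi[ok]), "")
  for (i in seq_along(chars)) mat[i, ] <- chars[[i]]
  match_ok <- rep(TRUE, sum(ok))
  for (j in seq_len(L)) {
    match_ok <- match_ok & mat[, j] %in% IUPAC_SETS[[codes[j]]]
  }
  ok[ok] <- match_ok
  ok
}

#' Read a BED file of genomic intervals
#'
#' Coordinates are kept in the BED convention: 0-based start, exclusive end.
#' A 4th column, when present, is preserved as `name`.
#'
#' @param path Path to a 3+ column tab-separated BED file (no header).
#' @return Tibble with columns `chrom`, `start`, `end`, `name` (`NA` when the
#'   file has only 3 columns). Empty files give an empty tibble.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED row ", which(nf < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    stop("BED row ", bad[1], ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop("BED row ", bad[1], ": start (", start[bad[1]],
         ") must be less than end (", end[bad[1]], ")")
  }
  if (any(start < 0)) {
    stop("BED row ", which(start < 0)[1], ": negative start coordinate")
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 NA_character_)
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR PFM layout: a `>ID NAME` header line followed by four
#' rows `A [ 1 2 3 ]`, `C [...]`, `G [...]`, `T [...]` (brackets optional).
#'
#' @param path Path to the PFM text file.
#' @return Named list of PFMs; each a 4 x L numeric matrix with rownames
#'   A, C, G, T. List names are motif IDs (`ID_NAME` when a name is present).
#' @seealso [write_jaspar_pfm()], [pfm_to_pwm()]
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no '>' motif headers found in ", path)
  out <- list()
  for (h in seq_along(headers)) {
    i <- headers[h]
    last <- if (h < length(headers)) headers[h + 1] - 1 else length(lines)
    block <- lines[(i + 1):last]
    if (length(block) != 4) {
      stop("motif block starting at line ", i, " has ", length(block),
           " base rows; expected 4 (A, C, G, T)")
    }
    hdr <- sub("^>\\s*", "", lines[i])
    parts <- strsplit(hdr, "\\s+")[[1]]
    id <- if (length(parts) >= 2) paste(parts[1], parts[2], sep = "_") else parts[1]
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(vals))) stop("non-numeric PFM entry in motif ", id)
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      stop("motif ", id, ": base rows have unequal lengths (",
           paste(lens, collapse = ", "), ")")
    }
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stop("motif ", id, ": negative counts")
    if (any(colSums(m) == 0)) stop("motif ", id, ": column with all-zero counts")
    out[[id]] <- m
  }
  out
}

#' Write position frequency matrices in JASPAR text format
#'
#' @param pfms Named list of 4 x L matrices (rows A, C, G, T).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    m <- pfms[[id]]
    writeLines(paste0(">", id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ", paste(m[b, ], collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Write a generic result table as TSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
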