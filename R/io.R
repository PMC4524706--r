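#' Read aligned DNA sequences from a FASTA file
#'
#' Sequences are returned uppercased, in file order, as a named character
#' vector (names are sample ids taken from the first whitespace-delimited
#' token of each header). The reader validates the alphabet (IUPAC DNA
#' letters, `N` and the gap character `-`) and reports parse problems with
#' the offending line number; it does not require equal lengths, which is
#' checked downstream by the alignment-based operations.
#'
#' @param path Path to a FASTA file. An empty file yields an empty vector.
#' @return Named character vector of uppercase DNA sequences.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("malformed FASTA: line ", line_no[1L], " is sequence data before any header")
  }
  ids <- character(0)
  seqs <- character(0)
  starts <- which(is_header)
  ends <- c(starts[-1L] - 1L, length(lines))
  for (h in seq_along(starts)) {
    header <- sub("^>", "", lines[starts[h]])
    id <- strsplit(trimws(header), "\\s+")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) {
      stop("malformed FASTA header (empty id) at line ", line_no[starts[h]])
    }
    if (ends[h] < starts[h] + 1L) {
      stop("empty sequence for record '", id, "' at line ", line_no[starts[h]])
    }
    body <- lines[(starts[h] + 1L):ends[h]]
    seq <- toupper(paste(gsub("\\s+", "", body), collapse = ""))
    bad <- regmatches(seq, regexpr("[^ACGTUMRWSYKVHDBN-]", seq))
    if (length(bad) > 0L) {
      stop("invalid character '", bad, "' in sequence '", id,
           "' (record starting at line ", line_no[starts[h]], ")")
    }
    ids <- c(ids, id)
    seqs <- c(seqs, seq)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a diploid microsatellite genotype table
#'
#' The central nuclear-data container: per (sample, locus) an unordered pair
#' of positive-integer allele labels (fragment sizes in bases), or missing.
#' Calls are stored with the smaller allele first so that unordered-pair
#' equality is plain matrix equality.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param locus_names Character vector of locus names.
#' @param a1,a2 Integer matrices (samples x loci) holding the two allele
#'   labels of each call; `NA` in both marks a missing call.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sample_ids, locus_names, a1, a2) {
  sample_ids <- as.character(sample_ids)
  locus_names <- as.character(locus_names)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in genotype table")
  a1 <- matrix(as.integer(a1), nrow = length(sample_ids),
               dimnames = list(sample_ids, locus_names))
  a2 <- matrix(as.integer(a2), nrow = length(sample_ids),
               dimnames = list(sample_ids, locus_names))
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing genotype call: both alleles must be typed or both missing")
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE)) {
    stop("allele labels must be positive integers")
  }
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  structure(list(sample_ids = sample_ids, locus_names = locus_names,
                 a1 = lo, a2 = hi),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$sample_ids), "samples x",
      length(x$locus_names), "loci;",
      sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param gt A `genotype_table`.
#' @return Integer count.
#' @export
n_samples <- function(gt) length(gt$sample_ids)

#' @rdname n_samples
#' @export
n_loci <- function(gt) length(gt$locus_names)

#' Read a genotype table
#'
#' Two dialects are supported. `"csv"` is the canonical self-describing form:
#' a header `id,<locus>a,<locus>b,...` with two columns per locus (suffixes
#' `a`/`b`). `"structure"` is the two-row-per-individual whitespace table
#' used by admixture software: each individual occupies two consecutive rows,
#' `id allele1 allele2 ...`, one allele row per chromosome. The missing-data
#' sentinel is configurable (default `-9`, with `0` also common).
#'
#' @param path Input path.
#' @param dialect `"csv"` or `"structure"`.
#' @param missing Character/numeric sentinel(s) marking a missing allele.
#' @param locus_names Optional locus names for the structure dialect
#'   (defaults `L1..Ln`).
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "structure"),
                           missing = "-9", locus_names = NULL) {
  dialect <- match.arg(dialect)
  missing <- as.character(missing)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          strip.white = TRUE)
    if (ncol(df) < 3L) stop("genotype CSV needs an id column plus locus columns")
    ids <- df[[1L]]
    cols <- names(df)[-1L]
    base <- sub("[ab]$", "", cols)
    suff <- substring(cols, nchar(cols))
    if (any(!suff %in% c("a", "b"))) {
      stop("genotype CSV locus columns must end in 'a' or 'b': ",
           paste(cols[!suff %in% c("a", "b")], collapse = ", "))
    }
    loci <- unique(base)
    for (l in loci) {
      if (sum(base == l) != 2L || !setequal(suff[base == l], c("a", "b"))) {
        stop("locus '", l, "' must have exactly two columns ('", l, "a', '", l, "b')")
      }
    }
    parse_col <- function(nm) {
      v <- df[[nm]]
      v[v %in% missing | v == ""] <- NA
      suppressWarnings(iv <- as.integer(v))
      if (any(is.na(iv) & !is.na(v))) {
        stop("non-integer allele in column '", nm, "'")
      }
      iv
    }
    a1 <- vapply(paste0(loci, "a"), parse_col, integer(length(ids)))
    a2 <- vapply(paste0(loci, "b"), parse_col, integer(length(ids)))
    if (length(ids) == 1L) { a1 <- rbind(a1); a2 <- rbind(a2) }
    genotype_table(ids, loci, a1, a2)
  } else {
    rows <- utils::read.table(path, header = FALSE, colClasses = "character",
                              strip.white = TRUE)
    if (nrow(rows) %% 2L != 0L) {
      stop("structure dialect requires two rows per individual; got ",
           nrow(rows), " rows")
    }
    odd <- rows[seq(1L, nrow(rows), by = 2L), , drop = FALSE]
    even <- rows[seq(2L, nrow(rows), by = 2L), , drop = FALSE]
    if (any(odd[[1L]] != even[[1L]])) {
      stop("paired rows must carry the same sample id")
    }
    nl <- ncol(rows) - 1L
    if (nl < 1L) stop("no locus columns found")
    if (is.null(locus_names)) locus_names <- paste0("L", seq_len(nl))
    if (length(locus_names) != nl) {
      stop("allele-field count per row (", nl, ") does not match locus_names (",
           length(locus_names), "): odd allele count for some locus")
    }
    to_int <- function(m) {
      v <- as.character(unlist(m[-1L], use.names = FALSE))
      v[v %in% missing] <- NA
      suppressWarnings(iv <- as.integer(v))
      if (any(is.na(iv) & !is.na(v))) stop("non-integer allele field")
      matrix(iv, nrow = nrow(m))
    }
    genotype_table(odd[[1L]], locus_names, to_int(odd), to_int(even))
  }
}

#' Write a genotype table in the canonical CSV dialect
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @param missing Sentinel written for missing calls (default `-9`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, missing = "-9") {
  out <- data.frame(id = gt$sample_ids, check.names = FALSE)
  for (j in seq_along(gt$locus_names)) {
    l <- gt$locus_names[j]
    va <- as.character(gt$a1[, j]); vb <- as.character(gt$a2[, j])
    va[is.na(va)] <- missing; vb[is.na(vb)] <- missing
    out[[paste0(l, "a")]] <- va
    out[[paste0(l, "b")]] <- vb
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the sample-metadata table
#'
#' A delimited table with header; required column `sample_id` (or `id`),
#' optional columns `region`, `latitude`, `longitude`, `mito_lineage`.
#' Coordinates, when present, are validated to lie on the globe.
#'
#' @param path Input path.
#' @param sep Field separator (default `","`).
#' @return A data frame with columns sample_id, region, latitude, longitude,
#'   mito_lineage (optional columns filled with `NA` when absent).
#' @export
read_metadata <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                          stringsAsFactors = FALSE)
  idcol <- intersect(c("sample_id", "id"), names(df))
  if (length(idcol) == 0L) stop("metadata needs a 'sample_id' (or 'id') column")
  ids <- as.character(df[[idcol[1L]]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pick <- function(col, cast = as.character) {
    if (col %in% names(df)) cast(df[[col]]) else cast(rep(NA, nrow(df)))
  }
  out <- data.frame(
    sample_id = ids,
    region = pick("region"),
    latitude = pick("latitude", as.numeric),
    longitude = pick("longitude", as.numeric),
    mito_lineage = pick("mito_lineage"),
    stringsAsFactors = FALSE
  )
  if (any(out$latitude < -90 | out$latitude > 90, na.rm = TRUE)) {
    stop("latitude out of [-90, 90]")
  }
  if (any(out$longitude < -180 | out$longitude > 180, na.rm = TRUE)) {
    stop("longitude out of [-180, 180]")
  }
  out
}
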