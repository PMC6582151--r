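#' Construct a marker grid
#'
#' The marker grid is the ordered set of biallelic SNV sites at which pooled
#' allele counts are observed or simulated. Allele A is by convention the
#' parent-1 (reference, N2-like) allele and allele B the parent-2
#' (CB4856-like) allele; all frequencies reported by the package are
#' frequencies of allele B unless stated otherwise.
#'
#' @param df Data frame with columns `chrom`, `bp` and optionally
#'   `allele_a`, `allele_b` (nucleotide identities, needed only for the
#'   bam-readcount dialect of [read_allele_counts()]).
#' @param map Optional [genetic_map()]; when given, every marker must lie
#'   within its chromosome's anchored span.
#' @return A tibble of class `marker_grid`, sorted by (chrom, bp).
#' @export
marker_grid <- function(df, map = NULL) {
  if (!all(c("chrom", "bp") %in% names(df))) {
    stop("marker grid needs columns chrom and bp")
  }
  df <- tibble::as_tibble(df)
  df$chrom <- as.character(df$chrom)
  if (!"allele_a" %in% names(df)) df$allele_a <- "A"
  if (!"allele_b" %in% names(df)) df$allele_b <- "B"
  if (anyDuplicated(df[c("chrom", "bp")]) > 0) {
    stop("duplicated (chrom, bp) keys in marker grid")
  }
  ord <- if (is.null(map)) unique(df$chrom) else map_chromosomes(map)
  df <- df[order(match(df$chrom, ord), df$bp), ]
  if (!is.null(map)) {
    for (ch in unique(df$chrom)) {
      sub <- map[map$chrom == ch, ]
      if (nrow(sub) == 0) stop("marker chromosome ", ch, " not in map")
      b <- df$bp[df$chrom == ch]
      if (any(b < min(sub$bp) | b > max(sub$bp))) {
        stop("markers outside the map span of chromosome ", ch)
      }
    }
  }
  structure(df, class = c("marker_grid", class(df)))
}

#' Read a marker grid from a VCF of SNV sites
#'
#' Keeps biallelic SNVs only; REF becomes allele A, ALT allele B.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param map Optional [genetic_map()] used to validate marker spans.
#' @return A [marker_grid()].
#' @export
read_marker_vcf <- function(path, map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_marker_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!snv)) {
    rlang::inform(sprintf("dropping %d non-SNV records", sum(!snv)))
  }
  fix <- fix[snv, , drop = FALSE]
  marker_grid(
    data.frame(
      chrom = fix$CHROM, bp = as.numeric(fix$POS),
      allele_a = fix$REF, allele_b = fix$ALT
    ),
    map = map
  )
}

#' Validate a table of pooled allele counts
#'
#' Per marker: `n1`/`n3` are allele-A/allele-B counts in the high (selected
#' or treatment) pool; `n2`/`n4` the same in the low (control) pool.
#' Markers whose control pool has zero depth are excluded (their baseline
#' frequency is undefined), with the exclusion count reported as a message.
#'
#' @param df Data frame with columns `chrom`, `pos`, `n1`, `n2`, `n3`, `n4`.
#' @return A tibble of class `allele_counts`, sorted by (chrom, pos).
#' @export
allele_counts <- function(df) {
  required <- c("chrom", "pos", "n1", "n2", "n3", "n4")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("allele-count table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df[required])
  df$chrom <- as.character(df$chrom)
  counts <- as.matrix(df[c("n1", "n2", "n3", "n4")])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("allele counts must be non-negative and non-missing")
  }
  zero_ctrl <- df$n2 + df$n4 == 0
  if (any(zero_ctrl)) {
    rlang::inform(sprintf(
      "excluding %d marker(s) with zero control-pool depth", sum(zero_ctrl)
    ))
    df <- df[!zero_ctrl, ]
  }
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos), ]
  structure(df, class = c("allele_counts", class(df)))
}

#' Read pooled allele counts
#'
#' Two dialects are supported. `"simple-tsv"` is a header-ed TSV with
#' columns `chrom`, `pos`, `refA_high`, `altB_high`, `refA_low`, `altB_low`
#' (the native format written by [simulate_pool_counts()] via
#' [write_allele_counts()]). `"bam-readcount"` parses the per-base count
#' fields of bam-readcount output for the two expected alleles of each
#' marker; it needs one file per pool and a marker grid carrying allele
#' identities. Bases other than the two expected alleles are ignored.
#'
#' @param path For `"simple-tsv"`: a single path. For `"bam-readcount"`: a
#'   named character vector `c(high = ..., low = ...)`.
#' @param dialect `"simple-tsv"` or `"bam-readcount"`.
#' @param markers Optional [marker_grid()]; required for the bam-readcount
#'   dialect. When given, the table is keyed to the grid and grid markers
#'   absent from the file are dropped with a message.
#' @return An [allele_counts()] tibble.
#' @export
read_allele_counts <- function(path, dialect = c("simple-tsv", "bam-readcount"),
                               markers = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "simple-tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("chrom", "pos", "refA_high", "altB_high", "refA_low", "altB_low")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      stop("simple-tsv counts file is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    tab <- tibble::tibble(
      chrom = as.character(df$chrom), pos = df$pos,
      n1 = df$refA_high, n3 = df$altB_high,
      n2 = df$refA_low, n4 = df$altB_low
    )
  } else {
    if (is.null(markers)) {
      stop("the bam-readcount dialect needs a marker grid with allele identities")
    }
    if (!all(c("high", "low") %in% names(path))) {
      stop("bam-readcount dialect needs path = c(high = ..., low = ...)")
    }
    hi <- parse_bam_readcount(path[["high"]], markers)
    lo <- parse_bam_readcount(path[["low"]], markers)
    tab <- tibble::tibble(
      chrom = markers$chrom, pos = markers$bp,
      n1 = hi$a, n3 = hi$b, n2 = lo$a, n4 = lo$b,
      found = hi$found & lo$found
    )
    tab <- tab[tab$found, setdiff(names(tab), "found")]
  }
  if (!is.null(markers)) {
    key <- paste(markers$chrom, markers$bp)
    in_file <- key %in% paste(tab$chrom, tab$pos)
    if (any(!in_file)) {
      rlang::inform(sprintf(
        "%d marker(s) of the grid absent from the counts file", sum(!in_file)
      ))
    }
    tab <- tab[paste(tab$chrom, tab$pos) %in% key, ]
  }
  allele_counts(tab)
}

# bam-readcount lines: chrom, pos, ref, depth, then one ':'-separated field
# per base whose first two elements are base and count.
parse_bam_readcount <- function(path, markers) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list(
    a = rep(NA_real_, nrow(markers)),
    b = rep(NA_real_, nrow(markers)),
    found = rep(FALSE, nrow(markers))
  )
  key <- paste(markers$chrom, markers$bp)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) next
    k <- match(paste(f[1], as.numeric(f[2])), key)
    if (is.na(k)) next
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    for (fld in f[5:length(f)]) {
      parts <- strsplit(fld, ":", fixed = TRUE)[[1]]
      if (length(parts) >= 2 && parts[1] %in% names(counts)) {
        counts[parts[1]] <- as.numeric(parts[2])
      }
    }
    out$a[k] <- unname(counts[markers$allele_a[k]])
    out$b[k] <- unname(counts[markers$allele_b[k]])
    out$found[k] <- TRUE
  }
  out$a[is.na(out$a)] <- 0
  out$b[is.na(out$b)] <- 0
  out
}

#' @rdname read_allele_counts
#' @param tab An [allele_counts()] table to write in the simple-tsv dialect.
#' @export
write_allele_counts <- function(tab, path) {
  readr::write_tsv(
    tibble::tibble(
      chrom = tab$chrom, pos = tab$pos,
      refA_high = tab$n1, altB_high = tab$n3,
      refA_low = tab$n2, altB_low = tab$n4
    ),
    path
  )
  invisible(path)
}
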