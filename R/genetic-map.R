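#' Construct a genetic map
#'
#' A genetic map is the bp-to-centimorgan backbone used both to place
#' crossovers during simulated meiosis and to define smoothing windows for
#' the pooled scan. It is stored as a tibble of anchor points, one or more
#' per chromosome, between which genetic position is linearly interpolated.
#' All coordinates are 1-based and inclusive (VCF convention).
#'
#' @param df A data frame with columns `chrom`, `bp` (integer-valued,
#'   >= 1) and `cm` (real, >= 0). Within each chromosome both `bp` and `cm`
#'   must be strictly increasing and the total map length must be positive.
#' @param x_chrom Label of the sex (X) chromosome, or `NA` if none.
#'
#' @return A tibble of class `genetic_map` with columns `chrom`, `bp`, `cm`
#'   and an `x_chrom` attribute.
#' @export
#' @examples
#' genetic_map(data.frame(
#'   chrom = "I", bp = c(1, 5e6, 1e7), cm = c(0, 10, 50)
#' ))
genetic_map <- function(df, x_chrom = NA_character_) {
  required <- c("chrom", "bp", "cm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("genetic map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df[required])
  df$chrom <- as.character(df$chrom)
  if (any(is.na(df$bp)) || any(is.na(df$cm))) stop("genetic map anchors contain NA")
  if (any(df$bp < 1)) stop("bp positions must be >= 1")
  if (any(df$cm < 0)) stop("cM positions must be >= 0")
  df <- df[order(match(df$chrom, unique(df$chrom)), df$bp), ]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) < 2) stop("chromosome ", ch, " needs at least two map anchors")
    if (any(diff(sub$bp) <= 0)) {
      stop("bp anchors not strictly increasing on chromosome ", ch)
    }
    if (any(diff(sub$cm) <= 0)) {
      stop("cM anchors not strictly increasing on chromosome ", ch)
    }
    if (max(sub$cm) - min(sub$cm) <= 0) {
      stop("chromosome ", ch, " has non-positive map length")
    }
  }
  if (!is.na(x_chrom) && !x_chrom %in% df$chrom) {
    stop("x_chrom '", x_chrom, "' is not a chromosome of the map")
  }
  structure(df, x_chrom = x_chrom, class = c("genetic_map", class(df)))
}

#' Read or write a genetic map TSV
#'
#' The on-disk format is a tab-separated file with a header row and columns
#' `chrom`, `bp`, `cm` (1-based inclusive bp coordinates).
#'
#' @param path Path to the TSV file.
#' @param x_chrom Label of the X chromosome (see [genetic_map()]).
#' @return For `read_genetic_map()`, a validated [genetic_map()].
#' @export
read_genetic_map <- function(path, x_chrom = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genetic_map(df, x_chrom = x_chrom)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()].
#' @return For `write_genetic_map()`, `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map)[c("chrom", "bp", "cm")], path)
  invisible(path)
}

map_chromosomes <- function(map) unique(map$chrom)

#' Chromosome spans of a genetic map
#'
#' @param map A [genetic_map()].
#' @return `chromosome_lengths()`: named vector of last-anchor bp positions;
#'   `map_lengths_cm()`: named vector of total map lengths in cM.
#' @export
chromosome_lengths <- function(map) {
  stats::setNames(
    vapply(map_chromosomes(map), function(ch) max(map$bp[map$chrom == ch]), 0),
    map_chromosomes(map)
  )
}

#' @rdname chromosome_lengths
#' @export
map_lengths_cm <- function(map) {
  stats::setNames(
    vapply(
      map_chromosomes(map),
      function(ch) diff(range(map$cm[map$chrom == ch])),
      0
    ),
    map_chromosomes(map)
  )
}

# Internal: genome description handed to the C++ core.
map_to_cpp <- function(map) {
  x <- attr(map, "x_chrom")
  lapply(map_chromosomes(map), function(ch) {
    sub <- map[map$chrom == ch, ]
    list(bp = as.numeric(sub$bp), cm = as.numeric(sub$cm),
         is_x = identical(ch, x))
  })
}

#' Interpolate between physical and genetic position
#'
#' Piecewise-linear interpolation between the map's anchors. `bp_to_cm()`
#' and `cm_to_bp()` are mutual inverses within each chromosome's anchored
#' span (up to floating point, since both are strictly monotone).
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome label (scalar).
#' @param bp,cm Positions to convert (vectorised). Values outside the
#'   chromosome's anchored span are an error.
#' @return Numeric vector of interpolated positions.
#' @export
bp_to_cm <- function(map, chrom, bp) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0) stop("chromosome ", chrom, " not in map")
  if (any(bp < min(sub$bp) | bp > max(sub$bp))) {
    stop("bp position outside the anchored span of chromosome ", chrom)
  }
  stats::approx(sub$bp, sub$cm, xout = bp, ties = "ordered")$y
}

#' @rdname bp_to_cm
#' @export
cm_to_bp <- function(map, chrom, cm) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0) stop("chromosome ", chrom, " not in map")
  if (any(cm < min(sub$cm) | cm > max(sub$cm))) {
    stop("cM position outside the anchored span of chromosome ", chrom)
  }
  stats::approx(sub$cm, sub$bp, xout = cm, ties = "ordered")$y
}
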