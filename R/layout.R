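#' Genome layouts for copy-number analysis
#'
#' A genome layout fixes the coordinate system every other function works in:
#' an ordered set of chromosomes with lengths, per-chromosome centromere
#' positions (so features can be attributed to p/q arms), and the bin size of
#' the count grid. All coordinates in the package are 0-based, half-open
#' (BED convention).
#'
#' Two layouts are built in. `"toy"` is a reduced 3-chromosome, 300 Mb genome
#' used throughout the documentation and tests: it keeps full pipelines at
#' desk-scale runtimes (10,000 bins at 30 kb) while exercising every code
#' path. `"grch37"` provides the 22 human autosomes at GRCh37 scale with
#' approximate centromere positions for users running realistic layouts.
#'
#' @param genome `"toy"` or `"grch37"`, or a data frame with columns
#'   `chrom`, `length`, `centromere` for a custom layout.
#' @param bin_size Bin width in bp (default 30000, i.e. 30 kb bins).
#' @return A `genome_layout` object: a list with `chromosomes` (tibble of
#'   `chrom`, `length`, `centromere`) and `bin_size`.
#' @examples
#' layout <- genome_layout("toy")
#' layout
#' @export
genome_layout <- function(genome = "toy", bin_size = 30000) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    stop_paircn("`bin_size` must be a single positive number", "paircn_config_error")
  }
  if (is.data.frame(genome)) {
    chroms <- as_tibble(genome)
    needed <- c("chrom", "length", "centromere")
    if (!all(needed %in% names(chroms))) {
      stop_paircn("custom layout needs columns chrom, length, centromere",
                  "paircn_config_error")
    }
    chroms <- chroms[, needed]
  } else if (identical(genome, "toy")) {
    chroms <- tibble(
      chrom = c("chr1", "chr2", "chr3"),
      length = c(120e6, 100e6, 80e6),
      centromere = c(60e6, 45e6, 35e6)
    )
  } else if (identical(genome, "grch37")) {
    chroms <- tibble(
      chrom = paste0("chr", 1:22),
      length = c(249250621, 243199373, 198022430, 191154276, 180915260,
                 171115067, 159138663, 146364022, 141213431, 135534747,
                 135006516, 133851895, 115169878, 107349540, 102531392,
                 90354753, 81195210, 78077248, 59128983, 63025520,
                 48129895, 51304566),
      centromere = c(125.0e6, 93.3e6, 91.0e6, 50.4e6, 48.4e6, 61.0e6,
                     59.9e6, 45.6e6, 49.0e6, 40.2e6, 53.7e6, 35.8e6,
                     17.9e6, 17.6e6, 19.0e6, 36.6e6, 24.0e6, 17.2e6,
                     26.5e6, 27.5e6, 13.2e6, 14.7e6)
    )
  } else {
    stop_paircn("unknown genome; use \"toy\", \"grch37\" or a data frame",
                "paircn_config_error")
  }
  if (any(chroms$length < bin_size)) {
    stop_paircn("all chromosome lengths must be >= bin_size", "paircn_config_error")
  }
  if (any(chroms$centromere <= 0 | chroms$centromere >= chroms$length)) {
    stop_paircn("centromeres must lie strictly inside their chromosome",
                "paircn_config_error")
  }
  structure(
    list(chromosomes = chroms, bin_size = as.numeric(bin_size)),
    class = "genome_layout"
  )
}

#' @export
#' @method print genome_layout
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosomes, ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp, bin size ",
      format(x$bin_size, big.mark = ","), " bp\n", sep = "")
  print(x$chromosomes)
  invisible(x)
}

genome_length <- function(layout) sum(layout$chromosomes$length)

#' Bin grid with GC and mappability annotations
#'
#' Tiles the genome into fixed-width bins (the last bin of each chromosome is
#' truncated at the chromosome end) and annotates each bin with a GC fraction
#' and a mappability fraction. The annotations are synthetic but structured
#' the way real bin annotation tracks are: GC varies smoothly along each
#' chromosome, mappability is near 1 for most of the genome, drops to 0 in a
#' 1 Mb window around each centromere, and a small fraction of isolated bins
#' have poor mappability.
#'
#' The same annotated grid must be shared by all samples of a cohort: the
#' bias model is a property of the genome, not of a sample.
#'
#' @param layout A [genome_layout()].
#' @param seed Integer seed controlling the annotation draw.
#' @param low_map_fraction Fraction of isolated bins given mappability below
#'   0.5 (default 0.01).
#' @return A tibble with `chrom`, `start`, `end`, `gc`, `mappability`.
#' @examples
#' bins <- layout_bins(genome_layout("toy"), seed = 1)
#' head(bins)
#' @export
layout_bins <- function(layout, seed = 1, low_map_fraction = 0.01) {
  stopifnot(inherits(layout, "genome_layout"))
  bs <- layout$bin_size
  grid <- purrr::pmap(layout$chromosomes, function(chrom, length, centromere) {
    start <- seq(0, length - 1, by = bs)
    tibble(chrom = chrom, start = start, end = pmin(start + bs, length),
           centromere = centromere)
  }) |> list_rbind()
  with_seed(seed, {
    mid <- (grid$start + grid$end) / 2
    chrom_idx <- match(grid$chrom, layout$chromosomes$chrom)
    phase <- runif(nrow(layout$chromosomes), 0, 2 * pi)
    # GC fluctuates mainly at sub-Mb scale so that it decorrelates from the
    # (much larger) copy-number segments; a weak Mb-scale wave adds realism
    gc <- 0.45 +
      0.015 * sin(2 * pi * mid / 2.1e6 + phase[chrom_idx]) +
      0.01 * sin(2 * pi * mid / 0.47e6 + 2 * phase[chrom_idx]) +
      rnorm(nrow(grid), 0, 0.035)
    gc <- pmin(pmax(gc, 0.30), 0.65)
    mappability <- rbeta(nrow(grid), 60, 1.5)
    low <- runif(nrow(grid)) < low_map_fraction
    mappability[low] <- runif(sum(low), 0, 0.5)
    near_cent <- abs(mid - grid$centromere) < 5e5
    mappability[near_cent] <- 0
    grid$gc <- gc
    grid$mappability <- mappability
  })
  grid$centromere <- NULL
  grid
}

# Split an interval table at centromeres and annotate the arm ("p"/"q").
split_by_arm <- function(intervals, layout) {
  cent <- setNames(layout$chromosomes$centromere, layout$chromosomes$chrom)
  missing <- setdiff(unique(intervals$chrom), names(cent))
  if (length(missing) > 0) {
    stop_paircn(paste0("no arm annotation for chromosome(s): ",
                       paste(missing, collapse = ", ")),
                "paircn_layout_error")
  }
  cm <- cent[intervals$chrom]
  spans <- intervals$start < cm & intervals$end > cm
  left <- intervals
  left$end <- pmin(intervals$end, cm)
  right <- intervals[spans, , drop = FALSE]
  right$start <- cm[spans]
  keep_left <- left$end > left$start
  out <- bind_rows(left[keep_left, , drop = FALSE], right)
  cm_out <- cent[out$chrom]
  out$arm <- ifelse(out$start < cm_out, "p", "q")
  arrange(out, match(.data$chrom, layout$chromosomes$chrom), .data$start)
}
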