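#' Run the full conservation-mutation correlation analysis
#'
#' Orchestrates the whole pipeline on one aligned family: read and validate
#' the alignment, build the position frequency matrix, delete gap-dominated
#' columns, compute the mutation matrix and both correlation matrices,
#' extract coupled pairs, cluster them into regions, assemble mutually
#' mutative groups, and write every result to `output_dir`.
#'
#' Files written: `frequency.tsv` (reduced 21 x L counts),
#' `position_map.json`, `mutation_matrix.tsv`, `r_con.tsv`, `r_mut.tsv`,
#' `pairs.tsv`, `report.json`, and with `plot = TRUE` also `r_con.png` /
#' `r_mut.png` (masked contour-style maps).
#'
#' @param input Path to an aligned FASTA file, or a `cmca_alignment`.
#' @param output_dir Output directory; created if absent.
#' @param gap_threshold Minimum natural-residue fraction to keep a column
#'   (strictly-below columns are deleted). Default 0.20.
#' @param pair_threshold Strict lower bound for coupled pairs. Default 0.80.
#' @param display_floor Mask floor for plots. Default 0.5.
#' @param include_gap_row Correlate profiles over all 21 types (default) or
#'   the 20 amino acids only.
#' @param region_radius Chebyshev linkage radius for region clustering.
#' @param min_group_size Smallest mutative group to report (>= 2).
#' @param reference Optional identifier of a reference sequence for dual
#'   numbering.
#' @param plot Also write PNG maps of both correlation matrices.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with `output_dir`, the `report`
#'   (`cmca_report`), the `position_map`, and both `cmca_cor` objects.
#' @examples
#' \donttest{
#' fam <- pdz_like_fixture()
#' out <- run_pipeline(fam$alignment, tempfile("cmca_run"))
#' out$report
#' }
#' @export
run_pipeline <- function(input, output_dir,
                         gap_threshold = 0.20,
                         pair_threshold = 0.80,
                         display_floor = 0.5,
                         include_gap_row = TRUE,
                         region_radius = 5L,
                         min_group_size = 2L,
                         reference = NULL,
                         plot = FALSE,
                         verbose = TRUE) {
  for (th in c(gap_threshold, pair_threshold, display_floor)) {
    if (!is.numeric(th) || length(th) != 1L || th < 0 || th > 1) {
      stop("thresholds must be single values in [0, 1]")
    }
  }
  if (region_radius < 0) stop("region_radius must be >= 0")
  if (min_group_size < 2) stop("min_group_size must be >= 2")

  say <- function(...) if (verbose) message("cmca: ", ...)

  checksum <- NA_character_
  if (inherits(input, "cmca_alignment")) {
    aln <- input
  } else {
    aln <- read_alignment(input)
    checksum <- unname(tools::md5sum(input))
  }
  say("alignment: N = ", aln$N, ", L0 = ", aln$L0)

  tensor <- encode_alignment(aln)
  freq0 <- position_frequencies(tensor)
  red <- reduce_gaps(freq0, threshold = gap_threshold)
  freq <- red$freq
  pm <- red$position_map
  say("gap reduction: ", freq0$L - freq$L, " column(s) deleted, L = ", freq$L)
  if (!is.null(reference)) {
    pm <- map_reference_numbering(aln, pm, reference)
  }

  mut <- mutation_matrix(freq)
  r_con <- conservation_correlation(freq, include_gap_row = include_gap_row)
  r_mut <- mutation_correlation(freq, include_gap_row = include_gap_row)

  pairs <- extract_pairs(r_mut, threshold = pair_threshold)
  pairs <- cluster_regions(pairs, radius = region_radius)
  groups <- build_groups(pairs, min_size = min_group_size)
  say(nrow(pairs), " coupled pair(s) above r = ", pair_threshold, ", ",
      length(groups), " group(s)")

  params <- list(
    gap_threshold = gap_threshold, pair_threshold = pair_threshold,
    display_floor = display_floor, include_gap_row = include_gap_row,
    region_radius = region_radius, min_group_size = min_group_size,
    reference = reference,
    package_version = as.character(utils::packageVersion("cmca")),
    input_md5 = checksum
  )
  report <- coupling_report(pairs, groups, pm,
                            undefined = r_mut$undefined, parameters = params)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_matrix(freq$counts, p("frequency.tsv"), corner = "symbol")
  write_position_map(pm, p("position_map.json"))
  write_matrix(mut$values, p("mutation_matrix.tsv"), corner = "symbol")
  write_matrix(r_con$values, p("r_con.tsv"))
  write_matrix(r_mut$values, p("r_mut.tsv"))
  write_pairs_tsv(report, p("pairs.tsv"))
  write_report_json(report, p("report.json"))
  if (plot) {
    for (fl in list(list(r_con, "r_con.png"), list(r_mut, "r_mut.png"))) {
      grDevices::png(p(fl[[2]]), width = 900, height = 900)
      plot_correlation_map(fl[[1]], floor = display_floor)
      grDevices::dev.off()
    }
  }
  say("results written to ", output_dir)
  invisible(list(output_dir = output_dir, report = report,
                 position_map = pm, r_con = r_con, r_mut = r_mut))
}

#' Contour-style map of a masked correlation matrix
#'
#' Draws the masked matrix with the conventional color bands: coefficients
#' in `[floor, 0.7)` light yellow, `[0.7, 0.8)` orange, `[0.8, 0.9)` pink
#' and `[0.9, 1]` red; everything below the floor and the diagonal is blank.
#'
#' @param corr A `cmca_cor` object.
#' @param floor Display floor (entries below are blanked). Default 0.5.
#' @param main Plot title; defaults to the matrix flavor.
#' @return Invisibly, the masked matrix.
#' @export
plot_correlation_map <- function(corr, floor = 0.5, main = NULL) {
  m <- filter_display(corr, floor = floor)
  L <- nrow(m)
  breaks <- sort(unique(c(floor, 0.7, 0.8, 0.9, 1 + 1e-9)))
  cols <- c("lightyellow", "orange", "pink", "red")[seq_len(length(breaks) - 1L)]
  graphics::image(
    x = seq_len(L), y = seq_len(L), z = t(m)[, L:1, drop = FALSE],
    breaks = breaks, col = cols, useRaster = FALSE,
    xlab = "position j", ylab = "position i", axes = FALSE,
    main = if (is.null(main)) paste0("position ", corr$flavor,
                                     " correlation (>= ", floor, ")") else main
  )
  at <- pretty(seq_len(L))
  at <- at[at >= 1 & at <= L]
  graphics::axis(1, at = at)
  graphics::axis(2, at = L + 1 - at, labels = at)
  graphics::box()
  invisible(m)
}
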