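# End-to-end orchestration: TPS input -> superimposition (with sliding) ->
# relative warps + broken stick -> pairwise Goodall battery, Kruskal-Wallis
# on angles, optional phylogenetic signal -> CSV/TPS/PNG outputs and a
# JSON run manifest.

#' Build and validate a run configuration
#'
#' @param tps_path TPS landmark file.
#' @param group_csv group table CSV (see [read_group_table()]).
#' @param scheme grouping-scheme column name in the group table.
#' @param angle_csv optional CSV with `specimen_id`, `group`, `angle_deg`.
#' @param tree_path optional newick/NEXUS phylogeny.
#' @param out_dir output directory (created if absent).
#' @param slide slide semi-landmarks during GPA (default `TRUE`).
#' @param n_permutations permutations per pairwise test (default 1999).
#' @param seed integer seed (mandatory).
#' @param alpha familywise base level (default 0.05).
#' @param exclude_groups group labels dropped before analysis (e.g. marine
#'   and winged taxa in a terrestrial analysis; default none).
#' @param make_plots write the ordination scatter PNG (default `TRUE`).
#' @return a validated `run_config` list.
#' @export
run_config <- function(tps_path, group_csv, scheme, angle_csv = NULL,
                       tree_path = NULL, out_dir = tempfile("radcurve_"),
                       slide = TRUE, n_permutations = 1999, seed,
                       alpha = 0.05, exclude_groups = character(),
                       make_plots = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  for (p in c(tps_path, group_csv, angle_csv, tree_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  cfg <- list(tps_path = tps_path, group_csv = group_csv, scheme = scheme,
              angle_csv = angle_csv, tree_path = tree_path,
              out_dir = out_dir, slide = slide,
              n_permutations = n_permutations, seed = as.integer(seed),
              alpha = alpha, exclude_groups = exclude_groups,
              make_plots = make_plots)
  grp <- read_group_table(group_csv, scheme = scheme)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[radcurve] %-12s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full posture-inference analysis
#'
#' Executes the whole pipeline on one grouping scheme: read and
#' side-standardize the TPS specimens, partial Procrustes superimposition
#' with minimum-bending-energy sliding, relative warp analysis with the
#' broken-stick assessment, the pairwise Goodall's F permutation battery
#' at the Bonferroni-corrected level, Kruskal-Wallis multiple comparisons
#' on the angle table when given, and per-axis Blomberg's K when a
#' phylogeny is given. Writes aligned coordinates (TPS and long CSV), a
#' GPA summary, relative warp scores, the variance table, the pairwise
#' F/p matrices plus the lower-triangle presentation table, angle and
#' phylogenetic-signal tables, an ordination plot with per-group convex
#' hulls, and a JSON manifest; reruns with the same config and seed
#' reproduce every CSV byte-for-byte.
#'
#' @param config a [run_config()] object.
#' @return (invisibly) list with `gpa`, `rw`, `variance`, `pairwise`,
#'   `kw`, `physig`, `files` (named vector of written paths), `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- c()

  dat <- .stage("input", {
    recs <- read_tps(config$tps_path)
    grp <- read_group_table(config$group_csv, scheme = config$scheme)
    if ("side" %in% names(grp)) recs <- standardize_sides(recs, grp)
    ids <- vapply(recs, `[[`, character(1), "id")
    lab <- grp[[config$scheme]][match(ids, grp$specimen_id)]
    keep <- !is.na(lab) & !(lab %in% config$exclude_groups)
    if (!any(keep)) stop("no specimens left after group filtering")
    list(coords = coords_array(structure(recs[keep],
                                         class = "tps_records")),
         labels = as.character(lab[keep]))
  })

  g <- .stage("gpa", gpa(dat$coords, slide = config$slide))
  write_tps(g$aligned, out("aligned.tps"))
  write.csv(aligned_long(g), out("aligned_long.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(specimen_id = names(g$distances),
                       group = dat$labels,
                       procrustes_distance = g$distances,
                       iterations = g$iterations,
                       converged = g$converged),
            out("gpa_summary.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, aligned_tps = out("aligned.tps"),
             aligned_long = out("aligned_long.csv"),
             gpa_summary = out("gpa_summary.csv"))

  rw <- .stage("warps", relative_warps(partial_warp_scores(g)))
  sc <- data.frame(specimen_id = rownames(rw$scores), group = dat$labels,
                   rw$scores, check.names = FALSE)
  write.csv(sc, out("relative_warp_scores.csv"), row.names = FALSE,
            quote = FALSE)
  vt <- variance_table(rw)
  write.csv(vt, out("variance_table.csv"), row.names = FALSE,
            quote = FALSE)
  files <- c(files, rw_scores = out("relative_warp_scores.csv"),
             variance = out("variance_table.csv"))

  pw <- .stage("pairwise", pairwise_shape_tests(
    dat$coords, dat$labels, n_permutations = config$n_permutations,
    seed = config$seed, alpha = config$alpha))
  write.csv(data.frame(group = rownames(pw$F), pw$F,
                       check.names = FALSE),
            out("pairwise_F.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(group = rownames(pw$p), pw$p,
                       check.names = FALSE),
            out("pairwise_p.csv"), row.names = FALSE, quote = FALSE)
  make_tables(pw, path = out("pairwise_table.csv"))
  files <- c(files, pairwise_F = out("pairwise_F.csv"),
             pairwise_p = out("pairwise_p.csv"),
             pairwise_table = out("pairwise_table.csv"))

  kw <- NULL
  if (!is.null(config$angle_csv)) {
    kw <- .stage("angles", {
      ang <- read.csv(config$angle_csv, stringsAsFactors = FALSE)
      kruskal_wallis_mc(ang$angle_deg, ang$group, alpha = config$alpha)
    })
    write.csv(data.frame(group = rownames(kw$p), kw$p,
                         check.names = FALSE),
              out("angle_kw_p.csv"), row.names = FALSE, quote = FALSE)
    files <- c(files, angle_kw = out("angle_kw_p.csv"))
  }

  physig <- NULL
  if (!is.null(config$tree_path)) {
    physig <- .stage("physignal", {
      tree <- if (grepl("\\.nex(us)?$", config$tree_path,
                        ignore.case = TRUE))
        ape::read.nexus(config$tree_path)
      else ape::read.tree(config$tree_path)
      sc_mat <- rw$scores
      rownames(sc_mat) <- rownames(rw$scores)
      keep_ax <- seq_len(min(5, ncol(sc_mat)))
      multivariate_k(tree, sc_mat[, keep_ax, drop = FALSE],
                     n_permutations = config$n_permutations,
                     seed = config$seed)
    })
    write.csv(physig$per_axis, out("phylo_signal.csv"),
              row.names = FALSE, quote = FALSE)
    files <- c(files, phylo_signal = out("phylo_signal.csv"))
  }

  if (config$make_plots) {
    ok <- tryCatch({
      grDevices::png(out("ordination.png"), width = 900, height = 700)
      plot_ordination(rw, dat$labels)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("plotting failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) files <- c(files, ordination = out("ordination.png"))
  }

  manifest <- list(
    package = "radcurve",
    version = as.character(utils::packageVersion("radcurve")),
    seed = config$seed,
    n_permutations = config$n_permutations,
    scheme = config$scheme,
    slide = config$slide,
    alpha = config$alpha,
    alpha_corrected = pw$alpha_corrected,
    config_hash = .config_hash(config),
    n_specimens = dim(dat$coords)[3],
    groups = as.list(table(dat$labels)),
    gpa_converged = g$converged,
    warnings = character())
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, manifest = out("manifest.json"))

  invisible(list(gpa = g, rw = rw, variance = vt, pairwise = pw, kw = kw,
                 physig = physig, labels = dat$labels, files = files,
                 manifest = manifest))
}

.config_hash <- function(config) {
  s <- paste(vapply(config[order(names(config))], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = "|")
  # tiny polynomial rolling hash; enough to fingerprint a config
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Render a pairwise battery as a lower-triangle table
#'
#' One row per group; the lower triangle holds the F value, starred when
#' the pair is significant at the Bonferroni-corrected level; upper
#' triangle and diagonal are blank. Untested pairs (singleton groups) are
#' blank too.
#'
#' @param pairwise a `pairwise_matrix`.
#' @param path optional CSV output path.
#' @param digits F-value digits (default 2, matching how such tables are
#'   usually printed).
#' @return character matrix of the rendered table, invisibly when `path`
#'   is given.
#' @export
make_tables <- function(pairwise, path = NULL, digits = 2) {
  stopifnot(inherits(pairwise, "pairwise_matrix"))
  gs <- pairwise$groups
  m <- matrix("", length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) for (j in seq_len(i - 1L)) {
    f <- pairwise$F[gs[i], gs[j]]
    if (is.na(f)) next
    star <- isTRUE(pairwise$significant[gs[i], gs[j]])
    m[i, j] <- paste0(formatC(f, format = "f", digits = digits),
                      if (star) "*" else "")
  }
  if (!is.null(path)) {
    tab <- data.frame(group = rownames(m), m, check.names = FALSE)
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(m))
  }
  m
}

#' Parse a lower-triangle pairwise table back to numbers
#'
#' Inverse of [make_tables()] (CSV form): recovers the F matrix and the
#' significance stars.
#'
#' @param path CSV written by [make_tables()].
#' @return list with `F` (numeric matrix) and `significant` (logical).
#' @export
parse_pairwise_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  gs <- tab$group
  cells <- as.matrix(tab[, -1, drop = FALSE])
  Fm <- matrix(NA_real_, length(gs), length(gs),
               dimnames = list(gs, gs))
  Sm <- matrix(NA, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    v <- cells[i, j]
    if (is.na(v) || v == "") next
    Sm[i, j] <- Sm[j, i] <- grepl("\\*$", v)
    Fm[i, j] <- Fm[j, i] <- as.numeric(sub("\\*$", "", v))
  }
  list(F = Fm, significant = Sm)
}

#' Relative warp ordination scatter with group convex hulls
#'
#' @param rw a `relative_warps` object.
#' @param labels per-specimen group labels.
#' @param axes which two axes to plot (default c(1, 2)).
#' @export
plot_ordination <- function(rw, labels, axes = c(1, 2)) {
  sc <- rw$scores[, axes, drop = FALSE]
  vp <- rw$variance_proportions[axes]
  groups <- unique(labels)
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
  graphics::plot(sc, type = "n",
                 xlab = sprintf("RW%d (%.1f%%)", axes[1], 100 * vp[1]),
                 ylab = sprintf("RW%d (%.1f%%)", axes[2], 100 * vp[2]))
  graphics::abline(h = 0, v = 0, col = "grey80")
  for (gi in seq_along(groups)) {
    pts <- sc[labels == groups[gi], , drop = FALSE]
    if (nrow(pts) >= 3) {
      hull <- grDevices::chull(pts)
      graphics::polygon(pts[hull, ], border = cols[gi],
                        col = grDevices::adjustcolor(cols[gi], 0.15))
    }
    graphics::points(pts, pch = 19, col = cols[gi])
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(
    groups)], pch = 19, bty = "n")
  invisible(NULL)
}
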