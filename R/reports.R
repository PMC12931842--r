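## End-to-end analysis runs: one Rips filtration, all requested invariant
## families, tabular export plus a manifest.  The default scale grid is the
## set of critical scales plus the midpoints between consecutive critical
## scales, so every open interval between transitions is sampled.

format_float_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.na(v)) NA_character_ else as.character(signif(v, 12))
      }, character(1))
    }
  }
  df
}

resolve_input <- function(input, atoms = "CA", chain = NULL) {
  if (inherits(input, "point_cloud"))
    return(list(cloud = input, source = "point_cloud"))
  if (!is.character(input) || length(input) != 1L)
    stop("input must be a point_cloud or a source string")
  if (grepl("^builtin:", input))
    return(list(cloud = fixture_cloud(input), source = input))
  if (grepl("^pdb:", input))
    return(list(cloud = read_pdb(sub("^pdb:", "", input), atoms, chain),
                source = input))
  if (grepl("^xyz:", input))
    return(list(cloud = read_xyz(sub("^xyz:", "", input)), source = input))
  stop(sprintf("unrecognized input '%s' (use builtin:NAME, pdb:FILE, xyz:FILE)",
               input))
}

default_grid <- function(crit) {
  if (length(crit) == 0L) return(0)
  mids <- if (length(crit) > 1L) (crit[-1L] + crit[-length(crit)]) / 2 else
    numeric(0)
  sort(unique(c(0, crit, mids)))
}

#' Run a full multiscale-invariant analysis
#'
#' Builds one Vietoris-Rips filtration from the input point cloud and writes
#' the requested invariant families as CSV (persistence barcode, Laplacian
#' spectrum curves, facet persistence barcode, f/h-vectors, graded Betti
#' tables) plus a JSON manifest recording the configuration.  Identical
#' configurations produce identical outputs.
#'
#' @param input a [point_cloud()], or a string `"builtin:NAME"`,
#'   `"pdb:FILE"`, `"xyz:FILE"`.
#' @param out_dir output directory (created if needed).
#' @param max_dim Rips truncation dimension (default 3).
#' @param grid scale grid; `NULL` (default) uses the critical scales plus
#'   midpoints between consecutive critical scales.
#' @param invariants subset of `"ph"`, `"pl"`, `"facets"`, `"fh"`,
#'   `"graded"`.
#' @param strands Hochster strands for the graded Betti section.
#' @param graded_budget vertex budget for exact Hochster enumeration; larger
#'   clouds have the graded section skipped with a warning (run status 3).
#' @param subset_sizes optional `i + j` restriction passed to
#'   [graded_betti()].
#' @param k_max largest Laplacian dimension for the spectrum curves.
#' @param atoms,chain PDB atom selection (see [read_pdb()]).
#' @return Invisibly, a list with `cloud`, `filtration`, `grid`, `files`
#'   (named paths), and `status` (0 success, 3 if a budgeted section was
#'   skipped).
#' @examples
#' \donttest{
#' out <- run_analysis("builtin:octagon", tempfile("octagon-run"))
#' read.csv(out$files[["barcode"]])
#' }
#' @export
run_analysis <- function(input, out_dir, max_dim = 3L, grid = NULL,
                         invariants = c("ph", "pl", "facets", "fh", "graded"),
                         strands = 1:3, graded_budget = 14L,
                         subset_sizes = NULL, k_max = 2L,
                         atoms = "CA", chain = NULL) {
  invariants <- match.arg(invariants, several.ok = TRUE)
  src <- resolve_input(input, atoms, chain)
  cloud <- src$cloud
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dm <- pairwise_distances(cloud)
  crit <- critical_scales(dm)
  if (is.null(grid)) grid <- default_grid(crit)
  fc <- rips_filtration(dm, max_dim = max_dim)
  files <- character(0)
  status <- 0L

  if ("ph" %in% invariants) {
    bc <- compute_barcode(fc)
    files["barcode"] <- file.path(out_dir, "barcode.csv")
    files["barcode_json"] <- file.path(out_dir, "barcode.json")
    write_barcode(bc, files[["barcode"]], files[["barcode_json"]])
  }
  if ("pl" %in% invariants) {
    sc <- spectrum_curves(fc, k_max = min(k_max, max_dim), grid = grid)
    files["spectra"] <- file.path(out_dir, "spectra.csv")
    utils::write.csv(format_float_df(sc), files[["spectra"]],
                     row.names = FALSE, quote = FALSE, na = "")
  }
  if ("facets" %in% invariants) {
    fb <- facet_barcode(fc)
    out <- fb
    out$death <- ifelse(is.infinite(out$death), NA_real_, out$death)
    files["facets"] <- file.path(out_dir, "facets.csv")
    utils::write.csv(format_float_df(out), files[["facets"]],
                     row.names = FALSE, quote = TRUE, na = "")
  }
  if ("fh" %in% invariants) {
    rows <- list()
    for (eps in grid) {
      fv <- f_vector(fc, eps)
      for (m in seq_along(fv$f)) {
        rows[[length(rows) + 1L]] <- data.frame(
          eps = eps, index = m - 1L, f = fv$f[m], h = fv$h[m])
      }
    }
    files["fh"] <- file.path(out_dir, "fh.csv")
    utils::write.csv(format_float_df(do.call(rbind, rows)), files[["fh"]],
                     row.names = FALSE, quote = FALSE)
  }
  if ("graded" %in% invariants) {
    if (n_points(cloud) > graded_budget && is.null(subset_sizes)) {
      warning(sprintf(
        "graded Betti section skipped: %d vertices exceed the budget (%d)",
        n_points(cloud), graded_budget))
      status <- 3L
    } else {
      rows <- list()
      for (eps in grid) {
        tab <- graded_betti(fc, eps, strands = strands,
                            subset_sizes = subset_sizes,
                            budget = graded_budget)
        if (nrow(tab) > 0L) {
          tab_df <- as.data.frame(tab)
          tab_df$eps <- eps
          tab_df$eps_prime <- eps
          rows[[length(rows) + 1L]] <-
            tab_df[, c("eps", "eps_prime", "i", "degree", "strand", "value")]
        }
      }
      gdf <- if (length(rows)) do.call(rbind, rows) else
        data.frame(eps = numeric(0), eps_prime = numeric(0), i = integer(0),
                   degree = integer(0), strand = integer(0),
                   value = integer(0))
      files["graded"] <- file.path(out_dir, "graded_betti.csv")
      utils::write.csv(format_float_df(gdf), files[["graded"]],
                       row.names = FALSE, quote = FALSE)
    }
  }

  coord_file <- tempfile()
  utils::write.table(src$cloud$coords, coord_file)
  manifest <- list(
    package = "ripstack",
    version = as.character(utils::packageVersion("ripstack")),
    r_version = R.version.string,
    input = src$source,
    input_md5 = unname(tools::md5sum(coord_file)),
    n_vertices = n_points(cloud),
    max_dim = max_dim,
    grid = grid,
    critical_scales = crit,
    invariants = invariants,
    strands = strands,
    status = status)
  unlink(coord_file)
  files["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(cloud = cloud, filtration = fc, grid = grid, files = files,
                 status = status))
}

#' Cross-framework consistency report for a result bundle
#'
#' Reads the exported tables of a [run_analysis()] bundle and checks, per
#' grid scale, the identities tying the frameworks together: the Betti number
#' read off the barcode must equal the harmonic multiplicity of the Laplacian
#' spectrum in every dimension, and the Euler characteristic from the
#' f-vector must equal the alternating Betti sum.  Sections absent from the
#' bundle yield `NA` columns and a partial report.
#'
#' @param bundle a [run_analysis()] result, or the path of its output
#'   directory.
#' @return Data frame with one row per scale and dimension present in the
#'   spectra table (or per scale only if the spectra section is missing):
#'   Betti numbers, harmonic multiplicities, Euler characteristics, and
#'   logical pass flags `ph_pl_ok`, `euler_ok`.
#' @export
compare_report <- function(bundle) {
  dir <- if (is.character(bundle)) bundle else
    dirname(bundle$files[["manifest"]])
  path <- function(f) file.path(dir, f)
  have <- function(f) file.exists(path(f))
  if (!have("barcode.csv"))
    stop("bundle must contain at least the persistent-homology section")
  bars <- utils::read.csv(path("barcode.csv"))
  bars$death[is.na(bars$death)] <- Inf
  betti_at <- function(k, eps) sum(bars$dim == k & bars$birth <= eps &
                                     bars$death > eps)
  spectra <- if (have("spectra.csv")) utils::read.csv(path("spectra.csv"))
             else NULL
  fh <- if (have("fh.csv")) utils::read.csv(path("fh.csv")) else NULL
  scales <- if (!is.null(spectra)) sort(unique(spectra$eps)) else
    if (!is.null(fh)) sort(unique(fh$eps)) else
      sort(unique(c(bars$birth, bars$death[is.finite(bars$death)])))
  ks <- if (!is.null(spectra)) sort(unique(spectra$k)) else 0:2
  all_ks <- 0:max(c(ks, bars$dim))   # Euler sums need every stored dimension
  rows <- lapply(scales, function(eps) {
    betti <- vapply(ks, betti_at, integer(1), eps = eps)
    betti_all <- vapply(all_ks, betti_at, integer(1), eps = eps)
    harm <- rep(NA_integer_, length(ks))
    if (!is.null(spectra)) {
      for (ii in seq_along(ks)) {
        hit <- spectra$k == ks[ii] & spectra$eps == eps
        if (any(hit)) {
          h <- spectra$harmonic_multiplicity[hit][1L]
          nk <- spectra$n_k[hit][1L]
          harm[ii] <- if (!is.na(nk) && nk == 0L) 0L else h
        }
      }
    }
    euler_f <- NA_real_
    if (!is.null(fh)) {
      sel <- fh$eps == eps & fh$index >= 1   # skip the f_-1 convention row
      if (any(sel))
        euler_f <- sum((-1)^(fh$index[sel] - 1) * fh$f[sel])
    }
    euler_b <- sum((-1)^all_ks * betti_all)
    data.frame(
      eps = eps,
      t(stats::setNames(betti, paste0("betti", ks))),
      t(stats::setNames(harm, paste0("harmonic", ks))),
      euler_f = euler_f, euler_betti = euler_b,
      ph_pl_ok = if (all(is.na(harm))) NA else
        all(betti[!is.na(harm)] == harm[!is.na(harm)]),
      euler_ok = if (is.na(euler_f)) NA else euler_f == euler_b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "partial") <- is.null(spectra) || is.null(fh)
  out
}
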