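ring_to_coords <- function(ring) {
  ring <- rbind(ring, ring[1, , drop = FALSE])   # close
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  m
}

#' Write core ranges as a GeoJSON FeatureCollection
#'
#' One Feature per range (RFC 7946 MultiPolygon geometry) with properties
#' `individual_id`, `season`, `year`.  Coordinates are planar metres, not
#' longitude/latitude; consumers must not reproject.
#'
#' @param ranges list of [core_range()] objects.
#' @param path output file.
#' @export
write_core_ranges_geojson <- function(ranges, path) {
  stopifnot(length(ranges) > 0)
  features <- lapply(ranges, function(r) {
    coords <- lapply(r$geometry$parts, function(part)
      lapply(part, ring_to_coords))
    list(type = "Feature",
         properties = list(individual_id = r$individual_id,
                           season = r$season, year = r$year),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read core ranges from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection with Polygon or MultiPolygon
#'   features carrying an `individual_id` property.
#' @return list of [core_range()] objects.
#' @export
read_core_ranges <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection")
  if (length(g$features) == 0L) stop("empty FeatureCollection")
  lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    id <- f$properties$individual_id
    if (is.null(id) || !nzchar(as.character(id)))
      stop(sprintf("feature %d: missing individual_id property", i))
    geom <- f$geometry
    if (is.null(geom$type))
      stop(sprintf("feature %d: missing geometry", i))
    coords <- geom$coordinates
    parts <- switch(geom$type,
      Polygon = list(lapply(coords, coords_to_ring)),
      MultiPolygon = lapply(coords, function(poly)
        lapply(poly, coords_to_ring)),
      stop(sprintf("feature %d: unsupported geometry type '%s'",
                   i, geom$type)))
    core_range(as.character(id), mp_geom(parts),
               season = if (is.null(f$properties$season)) "dry"
                        else f$properties$season,
               year = if (is.null(f$properties$year)) 0L
                      else as.integer(f$properties$year))
  })
}

geom_to_wkt <- function(g) {
  polys <- vapply(g$parts, function(part) {
    rings <- vapply(part, function(ring) {
      ring <- rbind(ring, ring[1, , drop = FALSE])
      paste0("(", paste(sprintf("%.10g %.10g", ring[, 1], ring[, 2]),
                        collapse = ", "), ")")
    }, "")
    paste0("(", paste(rings, collapse = ", "), ")")
  }, "")
  paste0("MULTIPOLYGON (", paste(polys, collapse = ", "), ")")
}

# split s at top-level commas (depth 0 w.r.t. parentheses)
split_top <- function(s) {
  depth <- 0L; start <- 1L; out <- character()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "," && depth == 0L) {
      out <- c(out, substr(s, start, i - 1L)); start <- i + 1L
    }
  }
  c(out, substr(s, start, nchar(s)))
}

strip_parens <- function(s) {
  s <- trimws(s)
  if (!startsWith(s, "(") || !endsWith(s, ")"))
    stop("malformed WKT: expected parenthesised group in '", s, "'")
  substr(s, 2L, nchar(s) - 1L)
}

wkt_to_geom <- function(wkt) {
  s <- trimws(wkt)
  if (grepl("^MULTIPOLYGON", s, ignore.case = TRUE)) {
    body <- strip_parens(sub("^MULTIPOLYGON\\s*", "", s, ignore.case = TRUE))
    polys <- split_top(body)
  } else if (grepl("^POLYGON", s, ignore.case = TRUE)) {
    polys <- sub("^POLYGON\\s*", "", s, ignore.case = TRUE)
  } else stop("unsupported WKT type in '", substr(s, 1, 30), "'")
  parts <- lapply(polys, function(p) {
    rings <- split_top(strip_parens(p))
    lapply(rings, function(r) {
      pts <- split_top(strip_parens(r))
      m <- do.call(rbind, lapply(pts, function(pt)
        as.numeric(strsplit(trimws(pt), "\\s+")[[1]][1:2])))
      n <- nrow(m)
      if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
      m
    })
  })
  mp_geom(parts)
}

#' Write / read core ranges as a WKT table (CSV)
#'
#' Columns: `individual_id`, `season`, `year`, `wkt` (MULTIPOLYGON).
#'
#' @param ranges list of [core_range()] objects.
#' @param path file path.
#' @export
write_core_ranges_wkt <- function(ranges, path) {
  stopifnot(length(ranges) > 0)
  df <- data.frame(
    individual_id = vapply(ranges, function(r) r$individual_id, ""),
    season = vapply(ranges, function(r) r$season, ""),
    year = vapply(ranges, function(r) r$year, 0L),
    wkt = vapply(ranges, function(r) geom_to_wkt(r$geometry), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_core_ranges_wkt
#' @export
read_core_ranges_wkt <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty WKT table")
  lapply(seq_len(nrow(df)), function(i)
    core_range(df$individual_id[i], wkt_to_geom(df$wkt[i]),
               season = df$season[i], year = df$year[i]))
}

#' Pipeline configuration
#'
#' @param input `NULL` to generate ranges from `generator`, or a path to a
#'   GeoJSON FeatureCollection (`.geojson`/`.json`) or WKT CSV.
#' @param generator a [generator_config()] used when `input` is `NULL`.
#' @param n_max maximal simplex size (default 6).
#' @param eps_area sliver threshold, hectares.
#' @param centrality_alpha filtration value for the centrality stage
#'   (default 4).
#' @param max_dim maximal homology dimension (default `n_max - 1`).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the report (the generator carries its
#'   own).
#' @param phenology `NULL` or a list with `n_species`, `n_periods`.
#' @param n_max_sweep `NULL` or integer vector of alternative n_max values
#'   for a robustness sweep of the centrality-by-size summary.
#' @param verbose logical; progress messages to stderr.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            n_max = 6L, eps_area = 1e-4,
                            centrality_alpha = 4, max_dim = n_max - 1L,
                            out_dir = tempfile("rangecomplex_run_"),
                            seed = 1L, phenology = NULL, n_max_sweep = NULL,
                            verbose = TRUE) {
  stopifnot(n_max >= 2, centrality_alpha >= 0, centrality_alpha <= 5,
            max_dim <= n_max - 1)
  structure(list(input = input, generator = generator, n_max = as.integer(n_max),
                 eps_area = eps_area, centrality_alpha = centrality_alpha,
                 max_dim = as.integer(max_dim), out_dir = out_dir,
                 seed = as.integer(seed), phenology = phenology,
                 n_max_sweep = n_max_sweep, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf(paste0("[rangecomplex] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' generate/read core ranges -> subset overlaps (Eq.-1-style ratios) ->
#' filtration indices -> downward-closed filtered complex -> persistence
#' barcode and Betti curves -> FCI and maximal simplicial degree centrality
#' (-> optional phenology table and IFA summary).  All stage outputs are
#' written under `config$out_dir` as GeoJSON/CSV plus a JSON run report with
#' parameters and output checksums; identical config and seed give identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the run report as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character()
  stage <- "read_input"
  report <- list(package = "rangecomplex",
                 version = as.character(utils::packageVersion("rangecomplex")),
                 parameters = list(n_max = config$n_max,
                                   eps_area = config$eps_area,
                                   centrality_alpha = config$centrality_alpha,
                                   max_dim = config$max_dim,
                                   f_alpha = "f(alpha) = 5 - alpha",
                                   seed = config$seed))
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (outputs so far: %s)",
                   name, conditionMessage(e),
                   paste(basename(written), collapse = ", ")), call. = FALSE))
  }

  ranges <- run_stage("input", {
    if (is.null(config$input)) {
      pipe_log(config, "generating %d synthetic core ranges (%s season)",
               config$generator$n_individuals, config$generator$season_label)
      gen_core_ranges(config$generator)
    } else if (grepl("\\.(geojson|json)$", config$input, ignore.case = TRUE)) {
      read_core_ranges(config$input)
    } else {
      read_core_ranges_wkt(config$input)
    }
  })
  report$n_individuals <- length(ranges)
  report$individual_ids <- vapply(ranges, function(r) r$individual_id, "")

  run_stage("write_ranges", {
    write_core_ranges_geojson(ranges, out("core_ranges.geojson"))
    write_core_ranges_wkt(ranges, out("core_ranges_wkt.csv"))
    written <- c(written, out("core_ranges.geojson"),
                  out("core_ranges_wkt.csv"))
  })

  table <- run_stage("overlaps", {
    pipe_log(config, "enumerating subset overlaps (n_max = %d)", config$n_max)
    tb <- enumerate_overlaps(ranges, n_max = config$n_max,
                             eps_area = config$eps_area)
    write_overlap_table(tb, out("overlaps.csv"))
    written <- c(written, out("overlaps.csv"))
    tb
  })
  report$n_overlap_records <- nrow(table)

  complex <- run_stage("filtration", {
    assign_entry_values(table,
                        vertex_universe = vapply(ranges, function(r)
                          r$individual_id, ""))
  })
  run_stage("write_complex", {
    utils::write.csv(as.data.frame(complex), out("complex.csv"),
                     row.names = FALSE)
    written <- c(written, out("complex.csv"))
  })

  bars <- run_stage("persistence", {
    pipe_log(config, "computing persistence (%d simplices)",
             length(complex$entries))
    b <- compute_persistence(complex, max_dim = config$max_dim)
    utils::write.csv(as.data.frame(b), out("barcode.csv"), row.names = FALSE)
    written <- c(written, out("barcode.csv"))
    b
  })
  report$n_bars_by_dim <- as.list(table(factor(bars$dimension,
                                               levels = 0:config$max_dim)))
  report$final_dimension <-
    max(vapply(names(complex$entries),
               function(k) length(split_key(k)) - 1L, 0L))

  curves <- run_stage("betti_curves", {
    cv <- lapply(0:config$max_dim, function(d) betti_curve(bars, d))
    df <- do.call(rbind, lapply(cv, function(c)
      data.frame(dimension = c$dimension, alpha = c$alpha, value = c$value)))
    utils::write.csv(df, out("betti_curves.csv"), row.names = FALSE)
    written <- c(written, out("betti_curves.csv"))
    cv
  })

  fci_res <- run_stage("fci", {
    r <- fci(curves, length(ranges), season = ranges[[1]]$season)
    utils::write.csv(data.frame(season = r$season, fci = r$value,
                                n_individuals = r$n_individuals),
                     out("fci.csv"), row.names = FALSE)
    written <- c(written, out("fci.csv"))
    r
  })
  report$fci <- fci_res$value

  centrality <- run_stage("centrality", {
    rec <- maximal_degree_centrality(complex, alpha = config$centrality_alpha)
    utils::write.csv(as.data.frame(rec), out("centrality.csv"),
                     row.names = FALSE)
    written <- c(written, out("centrality.csv"))
    if (nrow(rec) > 0) {
      utils::write.csv(centrality_by_size(rec), out("centrality_by_size.csv"),
                       row.names = FALSE)
      written <- c(written, out("centrality_by_size.csv"))
      if (length(unique(rec$size)) >= 4L) {
        fit <- fit_sigmoid(rec$size, rec$degree)
        utils::write.csv(data.frame(L = fit$L, k = fit$k, s0 = fit$s0,
                                    converged = fit$converged, rss = fit$rss),
                         out("sigmoid_fit.csv"), row.names = FALSE)
        written <- c(written, out("sigmoid_fit.csv"))
        report$sigmoid_converged <- fit$converged
      }
    } else {
      pipe_log(config, "centrality stage: empty subcomplex at alpha = %g",
               config$centrality_alpha)
    }
    rec
  })
  report$n_centrality_records <- nrow(centrality)

  if (!is.null(config$n_max_sweep)) {
    run_stage("n_max_sweep", {
      for (nm in config$n_max_sweep) {
        nm <- as.integer(nm)
        tb <- enumerate_overlaps(ranges, n_max = nm,
                                 eps_area = config$eps_area)
        cx <- assign_entry_values(tb, vertex_universe =
                                    vapply(ranges, function(r)
                                      r$individual_id, ""))
        rec <- maximal_degree_centrality(cx, alpha = config$centrality_alpha)
        if (nrow(rec) > 0) {
          f <- out(sprintf("centrality_by_size_nmax%d.csv", nm))
          utils::write.csv(centrality_by_size(rec), f, row.names = FALSE)
          written <- c(written, f)
        }
      }
    })
  }

  if (!is.null(config$phenology)) {
    run_stage("phenology", {
      ph <- gen_phenology(config$phenology$n_species,
                          config$phenology$n_periods, seed = config$seed)
      utils::write.csv(ph, out("phenology.csv"), row.names = FALSE)
      series <- ifa_series(ph)
      utils::write.csv(series, out("ifa.csv"), row.names = FALSE)
      s <- season_summary(series$IFA)
      utils::write.csv(data.frame(mean = s$mean, cv = s$cv),
                       out("ifa_summary.csv"), row.names = FALSE)
      written <- c(written, out("phenology.csv"), out("ifa.csv"),
                    out("ifa_summary.csv"))
    })
  }

  report$outputs <- as.list(tools::md5sum(sort(written)))
  names(report$outputs) <- basename(sort(written))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pipe_log(config, "done; %d output files in %s", length(written) + 1L,
           config$out_dir)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `overlaps`, `filtrate`, `persistence`, `metrics`,
#' `phenology`, `run-all`.  See `inst/cli/rangecomplex` for the launcher.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
rc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rangecomplex <command> [options]",
    "commands:",
    "  generate   --out DIR [--n N] [--season dry|wet] [--seed S]",
    "  overlaps   --ranges FILE --out DIR [--n-max K] [--eps-area H]",
    "  filtrate   --overlaps FILE --out DIR",
    "  persistence --overlaps FILE --out DIR [--max-dim D]",
    "  metrics    --overlaps FILE --out DIR [--alpha A]",
    "  phenology  --out DIR [--species N] [--periods N] [--seed S]",
    "  run-all    --out DIR [--ranges FILE] [--n N] [--season dry|wet]",
    "             [--seed S] [--n-max K]", sep = "\n")
  if (length(args) == 0L) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[[1L]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  getopt <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  outdir <- getopt("out", stop("--out is required"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)

  load_ranges <- function(path) {
    if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      read_core_ranges(path) else read_core_ranges_wkt(path)
  }
  load_table <- function(path) read_overlap_table(path)

  switch(cmd,
    "generate" = {
      cfg <- generator_config(
        n_individuals = num(getopt("n", 12)),
        seed = num(getopt("seed", 1)),
        season_label = getopt("season", "dry"))
      ranges <- gen_core_ranges(cfg)
      write_core_ranges_geojson(ranges, file.path(outdir, "core_ranges.geojson"))
      write_core_ranges_wkt(ranges, file.path(outdir, "core_ranges_wkt.csv"))
    },
    "overlaps" = {
      tb <- enumerate_overlaps(load_ranges(getopt("ranges",
                                                  stop("--ranges required"))),
                               n_max = num(getopt("n_max", 6)),
                               eps_area = num(getopt("eps_area", 1e-4)))
      write_overlap_table(tb, file.path(outdir, "overlaps.csv"))
    },
    "filtrate" = {
      cx <- assign_entry_values(load_table(getopt("overlaps",
                                                  stop("--overlaps required"))))
      utils::write.csv(as.data.frame(cx), file.path(outdir, "complex.csv"),
                       row.names = FALSE)
    },
    "persistence" = {
      cx <- assign_entry_values(load_table(getopt("overlaps",
                                                  stop("--overlaps required"))))
      md <- num(getopt("max_dim", cx$n_max - 1))
      bars <- compute_persistence(cx, max_dim = md)
      utils::write.csv(as.data.frame(bars), file.path(outdir, "barcode.csv"),
                       row.names = FALSE)
    },
    "metrics" = {
      cx <- assign_entry_values(load_table(getopt("overlaps",
                                                  stop("--overlaps required"))))
      bars <- compute_persistence(cx)
      curves <- lapply(0:(cx$n_max - 1L), function(d) betti_curve(bars, d))
      r <- fci(curves, length(cx$vertices))
      utils::write.csv(data.frame(fci = r$value,
                                  n_individuals = r$n_individuals),
                       file.path(outdir, "fci.csv"), row.names = FALSE)
      rec <- maximal_degree_centrality(cx, alpha = num(getopt("alpha", 4)))
      utils::write.csv(as.data.frame(rec), file.path(outdir, "centrality.csv"),
                       row.names = FALSE)
    },
    "phenology" = {
      ph <- gen_phenology(num(getopt("species", 16)),
                          num(getopt("periods", 12)),
                          seed = num(getopt("seed", 1)))
      utils::write.csv(ph, file.path(outdir, "phenology.csv"),
                       row.names = FALSE)
      utils::write.csv(ifa_series(ph), file.path(outdir, "ifa.csv"),
                       row.names = FALSE)
    },
    "run-all" = {
      cfg <- pipeline_config(
        input = getopt("ranges"),
        generator = generator_config(
          n_individuals = num(getopt("n", 12)),
          seed = num(getopt("seed", 1)),
          season_label = getopt("season", "dry")),
        n_max = num(getopt("n_max", 6)),
        out_dir = outdir, seed = num(getopt("seed", 1)))
      run_pipeline(cfg)
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}
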