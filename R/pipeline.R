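#' Default pipeline run configuration
#'
#' All constants the analysis uses are named here: 5 kb windows with a
#' 15-site minimum, MAF filter 0.05, K = 3 ancestries, 95th/99th F_ST
#' quantile flags, the 2.5% chromosome rule, a 0.90 karyotype posterior and
#' an EHH cutoff of 0.05.
#'
#' @param seed master seed; every randomized stage derives its own seed from
#'   it and the stage name.
#' @return Nested configuration list (serializable as YAML).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input = list(mode = "simulate", vcf = NULL, sample_sheet = NULL),
    simulate = list(preset = "study", n_chroms = 24L, sites_per_chrom = 5000L,
                    chrom_length_bp = 1000000L),
    stages = list(windows = TRUE, ancestry = TRUE, svscan = TRUE,
                  xpehh = FALSE, tree = FALSE),
    filter = list(maf = 0.05),
    windows = list(size = 5000L, min_sites = 15L, fst_method = "hudson",
                   quantiles = c(0.95, 0.99), chrom_rule = 0.025,
                   group_size = NULL),
    ancestry = list(K = 3L, n_sites = 5000L, n_restarts = 10L,
                    max_iter = 400L, tol = 1e-4, major = 0.80, minor = 0.10,
                    ref_locations = c(C = "NTH1", S = "STH1", M = "NTH2")),
    svscan = list(posterior = 0.90, use_local_pca = FALSE, gap = 2L),
    xpehh = list(cutoff = 0.05, max_gap = 200000L, core_step = 50L,
                 chroms = NULL),
    tree = list(min_homokaryotes = 6L)
  )
}

# internal: schema of known keys and validators
.cfg_schema <- function() {
  num <- function(lo, hi) function(x) is.numeric(x) && length(x) == 1 &&
    !is.na(x) && x >= lo && x <= hi
  int_pos <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0
  lgl <- function(x) is.logical(x) && length(x) == 1
  list(
    seed = int_pos,
    input = list(mode = function(x) x %in% c("simulate", "vcf"),
                 vcf = function(x) is.null(x) || is.character(x),
                 sample_sheet = function(x) is.null(x) || is.character(x)),
    simulate = list(preset = function(x) x %in% c("study"),
                    n_chroms = int_pos, sites_per_chrom = int_pos,
                    chrom_length_bp = int_pos),
    stages = list(windows = lgl, ancestry = lgl, svscan = lgl, xpehh = lgl,
                  tree = lgl),
    filter = list(maf = num(0, 0.499999)),
    windows = list(size = int_pos, min_sites = int_pos,
                   fst_method = function(x) x %in% c("hudson", "wc"),
                   quantiles = function(x) is.numeric(x) && length(x) == 2 &&
                     all(x > 0 & x < 1) && x[1] < x[2],
                   chrom_rule = num(0, 1),
                   group_size = function(x) is.null(x) || int_pos(x)),
    ancestry = list(K = function(x) int_pos(x) && x >= 2,
                    n_sites = int_pos, n_restarts = int_pos,
                    max_iter = int_pos, tol = num(0, 1), major = num(0, 1),
                    minor = num(0, 1),
                    ref_locations = function(x) is.character(x) &&
                      all(c("C", "S", "M") %in% names(x))),
    svscan = list(posterior = num(0, 1), use_local_pca = lgl,
                  gap = function(x) is.numeric(x) && x >= 0),
    xpehh = list(cutoff = num(0, 1), max_gap = int_pos, core_step = int_pos,
                 chroms = function(x) is.null(x) || is.character(x)),
    tree = list(min_homokaryotes = int_pos)
  )
}

#' Validate a pipeline configuration
#'
#' Checks every key against the schema before any stage runs; unknown keys
#' are reported with the closest known key as a suggestion.
#'
#' @param config a configuration list, or a path to a YAML file mirroring
#'   [default_run_config()].
#' @return The validated (merged-with-defaults) configuration, invisibly on
#'   success; errors describe every offending key.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  schema <- .cfg_schema()
  defaults <- default_run_config()
  errors <- character()
  walk <- function(cfg, sch, path) {
    for (key in names(cfg)) {
      full <- if (nzchar(path)) paste0(path, ".", key) else key
      if (!key %in% names(sch)) {
        near <- names(sch)[which.min(utils::adist(key, names(sch)))]
        errors <<- c(errors, paste0("unknown key '", full,
                                    "' (did you mean '", near, "'?)"))
        next
      }
      if (is.function(sch[[key]])) {
        if (!isTRUE(sch[[key]](cfg[[key]]))) {
          errors <<- c(errors, paste0("invalid value for '", full, "'"))
        }
      } else {
        if (!is.list(cfg[[key]])) {
          errors <<- c(errors, paste0("'", full, "' must be a section"))
        } else {
          walk(cfg[[key]], sch[[key]], full)
        }
      }
    }
  }
  walk(config, schema, "")
  if (length(errors)) stop("invalid config:\n  ",
                           paste(errors, collapse = "\n  "))
  merged <- utils::modifyList(defaults, config)
  invisible(merged)
}

# internal: deterministic per-stage seed below 2^31
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 10007L + as.integer(h)) %% 2147483587L
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> MAF filter -> windowed landscapes (three
#' pairwise cluster comparisons with quantile flags and the chromosome SV
#' rule) -> ancestry EM and ternary classes -> SV karyotyping with southern
#' polarization -> optional XP-EHH scan and SV-region NJ trees, writing all
#' outputs plus a machine-readable run report under `out_dir`.
#'
#' @param config configuration list or YAML path (see [validate_config()]).
#' @param out_dir output directory (created).
#' @return The run report (also written as `report.json`), containing stage
#'   parameter echoes, output digests, warnings, wall times and summary
#'   counts.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile()) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg, stages = list(), warnings = character())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- withCallingHandlers(expr, warning = function(w) {
      report$warnings <<- c(report$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    list(value = v, wall = proc.time()[["elapsed"]] - t0)
  }
  digest <- function(path) unname(tools::md5sum(path))

  ## input stage -------------------------------------------------------
  st <- t_stage({
    if (cfg$input$mode == "simulate") {
      sc <- default_study_config(seed = .stage_seed(cfg$seed, "simulate"),
                                 n_chroms = cfg$simulate$n_chroms,
                                 sites_per_chrom = cfg$simulate$sites_per_chrom,
                                 chrom_length_bp = cfg$simulate$chrom_length_bp)
      sim <- simulate_study(sc)
      write_vcf(sim$gm, file.path(out_dir, "simulated.vcf"))
      write_sample_sheet(sim$sample_sheet, file.path(out_dir, "samples.tsv"))
      write_truth(sim$truth, file.path(out_dir, "truth.json"))
      sim
    } else {
      if (is.null(cfg$input$vcf)) stop("input.vcf required in vcf mode")
      gm <- read_vcf(cfg$input$vcf)
      sheet <- if (!is.null(cfg$input$sample_sheet)) {
        read_sample_sheet(cfg$input$sample_sheet, gm)
      } else NULL
      list(gm = gm, truth = NULL, sample_sheet = sheet)
    }
  })
  sim <- st$value
  report$stages$input <- list(wall = st$wall,
                              n_samples = length(sim$gm$samples),
                              n_sites = nrow(sim$gm$sites))

  ## MAF filter --------------------------------------------------------
  st <- t_stage(filter_maf(sim$gm, cfg$filter$maf))
  gm <- st$value
  report$stages$filter <- list(wall = st$wall, maf = cfg$filter$maf,
                               n_sites = nrow(gm$sites))

  ## ancestry ----------------------------------------------------------
  profiles <- NULL
  if (isTRUE(cfg$stages$ancestry)) {
    st <- t_stage({
      set.seed(.stage_seed(cfg$seed, "ancestry"))
      idx <- sort(sample.int(nrow(gm$sites),
                             min(cfg$ancestry$n_sites, nrow(gm$sites))))
      fit <- admixture_em(gm_subset(gm, sites = idx), K = cfg$ancestry$K,
                          seed = .stage_seed(cfg$seed, "ancestry-em"),
                          max_iter = cfg$ancestry$max_iter,
                          tol = cfg$ancestry$tol,
                          n_restarts = cfg$ancestry$n_restarts)
      refs <- lapply(cfg$ancestry$ref_locations, function(loc) {
        sim$sample_sheet$sample_id[sim$sample_sheet$location == loc]
      })
      if (any(lengths(refs) == 0)) {
        stop("ancestry reference locations missing from the sample sheet")
      }
      Q <- align_q(fit$Q, refs)
      pr <- ancestry_profiles(Q, cfg$ancestry$major, cfg$ancestry$minor)
      utils::write.table(pr, file.path(out_dir, "ancestry.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(fit = fit, profiles = pr)
    })
    profiles <- st$value$profiles
    report$stages$ancestry <- list(
      wall = st$wall, K = cfg$ancestry$K,
      loglik = st$value$fit$loglik,
      converged = st$value$fit$converged,
      class_counts = as.list(table(profiles$class)),
      digest = digest(file.path(out_dir, "ancestry.tsv")))
  }

  ## windowed landscapes ------------------------------------------------
  stat_tables <- NULL; chrom_flags <- NULL
  if (isTRUE(cfg$stages$windows)) {
    if (is.null(profiles)) stop("windows stage requires the ancestry stage ",
                                "(cluster comparisons need classes)")
    st <- t_stage({
      w <- make_windows(gm$sites, size = cfg$windows$size,
                        min_sites = cfg$windows$min_sites)
      grp <- function(cl) {
        ids <- profiles$sample_id[profiles$class == cl]
        gs <- cfg$windows$group_size
        if (!is.null(gs) && length(ids) > gs) ids[seq_len(gs)] else ids
      }
      pairs <- list(CM = c("C", "M"), CS = c("C", "S"), SM = c("S", "M"))
      tabs <- lapply(pairs, function(pp) {
        tab <- window_stats(gm, grp(pp[1]), grp(pp[2]), w,
                            method = cfg$windows$fst_method)
        quantile_flags(tab, probs = cfg$windows$quantiles)
      })
      flags <- lapply(tabs, chromosome_sv_flag,
                      threshold = cfg$windows$chrom_rule)
      for (nm in names(tabs)) {
        utils::write.table(tabs[[nm]],
                           file.path(out_dir, paste0("windows_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(tabs = tabs, flags = flags)
    })
    stat_tables <- st$value$tabs
    chrom_flags <- st$value$flags
    flagged <- sort(unique(unlist(lapply(chrom_flags,
                                         function(f) f$chrom[f$sv_flag]))))
    report$stages$windows <- list(
      wall = st$wall, size = cfg$windows$size,
      min_sites = cfg$windows$min_sites, method = cfg$windows$fst_method,
      flagged_chromosomes = flagged,
      digest = digest(file.path(out_dir, "windows_CM.tsv")))
  }

  ## SV karyotyping ----------------------------------------------------
  sv_calls <- NULL
  if (isTRUE(cfg$stages$svscan)) {
    if (is.null(stat_tables) || is.null(profiles)) {
      stop("svscan stage requires the windows and ancestry stages")
    }
    st <- t_stage({
      flagged <- sort(unique(unlist(lapply(chrom_flags,
                                           function(f) f$chrom[f$sv_flag]))))
      # per chromosome, use the comparison with the strongest flag signal
      best_tab <- function(ch) {
        fr <- vapply(chrom_flags, function(f) {
          i <- match(ch, f$chrom); if (is.na(i)) 0 else f$frac[i]
        }, numeric(1))
        stat_tables[[which.max(fr)]]
      }
      calls <- list()
      for (ch in flagged) {
        tab <- best_tab(ch)
        calls[ch] <- sv_scan(gm, profiles, ch,
                             tab[tab$chrom == ch, , drop = FALSE],
                             posterior = cfg$svscan$posterior,
                             use_local_pca = cfg$svscan$use_local_pca,
                             sample_sheet = sim$sample_sheet)
      }
      kdf <- do.call(rbind, lapply(calls, function(x) {
        if (is.null(x$calls)) return(NULL)
        cbind(chrom = x$chrom, x$calls)
      }))
      if (!is.null(kdf)) {
        utils::write.table(kdf, file.path(out_dir, "karyotypes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      blocks <- do.call(rbind, lapply(calls, `[[`, "block"))
      if (!is.null(blocks) && nrow(blocks)) {
        utils::write.table(blocks, file.path(out_dir, "sv_blocks.bed"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
      calls
    })
    sv_calls <- st$value
    report$stages$svscan <- list(
      wall = st$wall, posterior = cfg$svscan$posterior,
      n_sv_called = sum(vapply(sv_calls, function(x) !is.null(x$calls),
                               logical(1))),
      polarized = vapply(sv_calls, `[[`, logical(1), "polarized"))
  }

  ## XP-EHH ------------------------------------------------------------
  if (isTRUE(cfg$stages$xpehh)) {
    if (is.null(profiles)) stop("xpehh stage requires the ancestry stage")
    st <- t_stage({
      chroms <- cfg$xpehh$chroms %||% unique(gm$sites$chrom)
      popA <- profiles$sample_id[profiles$class == "C"]
      popB <- profiles$sample_id[profiles$class == "M"]
      keep <- gm$sites$chrom %in% chroms
      cores <- which(keep)[seq(1, sum(keep), by = cfg$xpehh$core_step)]
      sc <- xpehh_scan(gm, popA, popB, cores = cores,
                       cutoff = cfg$xpehh$cutoff,
                       max_gap = cfg$xpehh$max_gap)
      utils::write.table(sc, file.path(out_dir, "xpehh.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sc
    })
    report$stages$xpehh <- list(wall = st$wall, cutoff = cfg$xpehh$cutoff,
                                n_cores = nrow(st$value),
                                digest = digest(file.path(out_dir,
                                                          "xpehh.tsv")))
  }

  ## SV-region trees ---------------------------------------------------
  if (isTRUE(cfg$stages$tree)) {
    if (is.null(sv_calls)) stop("tree stage requires the svscan stage")
    st <- t_stage({
      trees <- list()
      for (x in sv_calls) {
        if (is.null(x$calls) || is.null(x$block) || nrow(x$block) == 0) next
        ids <- subset_homokaryotes(gm, x$calls)
        if (length(ids) < cfg$tree$min_homokaryotes) next
        reg <- list(chrom = x$chrom, start = x$block$start[1],
                    end = x$block$end[nrow(x$block)])
        dm <- diff_matrix(gm, region = reg, samples = ids)
        tr <- nj_tree(dm)
        g00 <- intersect(ids, x$calls$sample_id[x$calls$genotype == "00"])
        g11 <- intersect(ids, x$calls$sample_id[x$calls$genotype == "11"])
        tr <- tryCatch(root_between_groups(tr, g00, g11),
                       error = function(e) {
                         warning("could not root ", x$chrom, ": ",
                                 conditionMessage(e))
                         tr
                       })
        trees[[x$chrom]] <- tr
      }
      if (length(trees)) {
        ape::write.tree(do.call(c, trees),
                        file.path(out_dir, "sv_trees.nwk"))
      }
      trees
    })
    report$stages$tree <- list(wall = st$wall, n_trees = length(st$value))
  }

  report$summary <- list(
    n_samples = length(gm$samples), n_sites = nrow(gm$sites),
    flagged_chromosomes = report$stages$windows$flagged_chromosomes,
    n_sv_called = report$stages$svscan$n_sv_called,
    class_counts = report$stages$ancestry$class_counts)
  jsonlite::write_json(report[setdiff(names(report), "config")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
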