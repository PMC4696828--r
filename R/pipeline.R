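#' Available scoring methods
#'
#' @return Character vector of the eleven built-in method names accepted
#'   by [score_method()].
#' @export
score_methods <- function() {
  c("pearson", "spearman", "kendall", "dcov", "hoeffding", "rdc", "mi",
    "ida", "lasso", "elastic", "zscore")
}

#' Run one scoring method by name
#'
#' Dispatch layer used by the ensemble and the command-line driver; every
#' method receives the dataset and its own parameters and returns a
#' [score_matrix()].
#'
#' @param ds An [expr_dataset()].
#' @param method One of [score_methods()].
#' @param ... Method parameters (`seed`, `alpha`, `bins`, `lambda`, ...).
#' @return A `mir_scores` matrix.
#' @export
score_method <- function(ds, method, ...) {
  fns <- list(pearson = score_pearson, spearman = score_spearman,
              kendall = score_kendall, dcov = score_dcov,
              hoeffding = score_hoeffding, rdc = score_rdc,
              mi = score_mi, ida = score_ida, lasso = score_lasso,
              elastic = score_elastic, zscore = score_zscore)
  if (!method %in% names(fns)) {
    stop("unknown method '", method, "'; available: ",
         paste(score_methods(), collapse = ", "), call. = FALSE)
  }
  fn <- fns[[method]]
  args <- list(...)
  args <- args[intersect(names(args), names(formals(fn)))]
  do.call(fn, c(list(ds), args))
}

#' Run a declarative analysis pipeline
#'
#' Executes the whole dry-lab workflow from one YAML (or list) config:
#' simulate or load a dataset, score it with one or more methods,
#' optionally aggregate (Borda), mask by sequence-based target pairs,
#' validate against both ground-truth types, and compare methods.  Every
#' artefact is written under `out_dir`; all randomness derives from the
#' config's single `seed`.
#'
#' Config keys (all optional unless noted):
#' \describe{
#'   \item{dataset}{`path` + `cause`/`effect` 1-based ranges, or
#'     `synthetic: true` with generator parameters.}
#'   \item{methods}{Character vector of [score_methods()] (or `"all"`),
#'     plus optional per-method parameter blocks.}
#'   \item{ensemble}{`type: borda` or `borda_topk` with `k`.}
#'   \item{mask}{Path of a `miRNA,mRNA` binding-pair CSV.}
#'   \item{validate}{`topk` (vector), `truth`/`perturbation` paths
#'     (defaults to the simulated ones), `lfc_threshold`.}
#'   \item{external}{Paths of external score CSVs to ingest and compare.}
#'   \item{out_dir}{Output directory (required).}
#'   \item{seed}{Top-level integer seed.}
#' }
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @return Invisibly, a list with the dataset, score matrices, reports
#'   and comparison tables produced.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("mirlens %s | seed %d", as.character(utils::packageVersion("mirlens")),
       as.integer(seed))

  # --- dataset -----------------------------------------------------------
  sim <- NULL
  if (isTRUE(cfg$dataset$synthetic)) {
    gen_args <- cfg$dataset[intersect(names(cfg$dataset),
                                      names(formals(simulate_regulation)))]
    gen_args$seed <- gen_args$seed %||% seed
    sim <- do.call(simulate_regulation, gen_args)
    ds <- sim$dataset
    write_simulation(sim, file.path(out_dir, "synthetic"), gen_args)
    logf("simulated dataset: %d samples, %d miRNAs, %d mRNAs, %d edges",
         nrow(ds$exprs), n_mirna(ds), n_mrna(ds), nrow(sim$edges))
  } else if (!is.null(cfg$dataset$path)) {
    ds <- read_expression(cfg$dataset$path,
                          cause = range_to_idx(cfg$dataset$cause),
                          effect = range_to_idx(cfg$dataset$effect))
    logf("loaded %s", cfg$dataset$path)
  } else {
    stop("config needs dataset$path or dataset$synthetic: true",
         call. = FALSE)
  }

  # --- scoring -----------------------------------------------------------
  methods <- cfg$methods %||% character()
  if (identical(methods, "all") || "all" %in% methods) {
    methods <- score_methods()
  }
  params <- cfg$method_params %||% list()
  scores <- list()
  for (m in methods) {
    args <- params[[m]] %||% list()
    args$seed <- args$seed %||% seed
    sm <- do.call(score_method, c(list(ds, m), args))
    scores[[m]] <- sm
    write_scores(sm, file.path(out_dir, paste0("scores_", m, ".csv")))
    logf("scored %s (%s)", m, attr(sm, "ordering"))
  }

  # --- external results --------------------------------------------------
  for (path in cfg$external %||% character()) {
    lbl <- tools::file_path_sans_ext(basename(path))
    scores[[lbl]] <- read_external_result(ds, path)
    logf("ingested external result %s", path)
  }

  # --- ensemble ----------------------------------------------------------
  if (!is.null(cfg$ensemble) && length(scores) >= 2) {
    ens <- if (identical(cfg$ensemble$type, "borda_topk")) {
      borda_topk(scores, k = cfg$ensemble$k)
    } else borda(scores)
    scores[["ensemble"]] <- ens
    write_scores(ens, file.path(out_dir, "scores_ensemble.csv"))
    logf("ensemble: %s over %d methods",
         cfg$ensemble$type %||% "borda", length(scores) - 1L)
  }

  # --- mask --------------------------------------------------------------
  if (!is.null(cfg$mask)) {
    binding <- read_ground_truth(cfg$mask)
    scores <- lapply(scores, apply_target_mask, binding = binding)
    logf("masked all score matrices by %s (%d pairs)",
         cfg$mask, nrow(binding))
  }

  # --- validation & comparison ------------------------------------------
  results <- list(dataset = ds, simulation = sim, scores = scores)
  if (!is.null(cfg$validate)) {
    truth <- cfg$validate$truth %||%
      (if (!is.null(sim)) sim$truth else NULL)
    if (is.character(truth)) truth <- read_ground_truth(truth)
    pert <- cfg$validate$perturbation %||%
      (if (!is.null(sim)) sim$perturbation else NULL)
    if (is.character(pert)) pert <- read_perturbation(pert)
    lfc_thr <- cfg$validate$lfc_threshold %||% 1.0
    ks <- cfg$validate$topk %||% 100
    ks <- ks[ks <= n_mrna(ds)]
    reports <- list()
    for (m in names(scores)) {
      rk <- to_ranking(scores[[m]])
      for (k in ks) {
        v <- validate_all(rk, k, truth, pert, lfc_thr)
        for (type in names(v)) {
          reports[[paste(m, k, type, sep = "_")]] <- v[[type]]
          write_validation(
            v[[type]],
            path_json = file.path(out_dir, sprintf(
              "validation_%s_k%d_%s.json", m, k, type)))
          logf("validated %s k=%d (%s): %d confirmed",
               m, k, type, v[[type]]$total)
        }
      }
    }
    results$reports <- reports
    if (length(scores) >= 2) {
      comparisons <- list()
      for (k in ks) {
        for (type in c("confirmed", "perturbation")) {
          sel <- reports[paste(names(scores), k, type, sep = "_")]
          sel <- sel[!vapply(sel, is.null, logical(1))]
          if (length(sel) >= 2) {
            names(sel) <- sub(paste0("_", k, "_", type, "$"), "",
                              names(sel))
            cmp <- compare_methods(sel)
            comparisons[[paste(type, k, sep = "_")]] <- cmp
            write_csv_lf(as.data.frame(cmp), file.path(
              out_dir, sprintf("comparison_k%d_%s.csv", k, type)))
            logf("compared %d methods at k=%d (%s)", length(sel), k, type)
          }
        }
      }
      results$comparisons <- comparisons
    }
  }
  invisible(results)
}

# accept "1:35", c(1, 35), or a plain vector of indices
range_to_idx <- function(x) {
  if (is.character(x) && grepl(":", x)) {
    parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    return(parts[1]:parts[2])
  }
  if (is.numeric(x) && length(x) == 2) return(x[1]:x[2])
  as.integer(x)
}
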