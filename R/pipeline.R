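#' Pipeline configuration
#'
#' Everything one analysis run needs, with every seed explicit. The input
#' is either a simulated cohort (`simulate = TRUE`, using
#' [cohort_preset()] scaled to `n_participants`) or a recall CSV written
#' in the tidy format of [write_recalls()].
#'
#' @param simulate Simulate the cohort (TRUE) or read `recalls_path`?
#' @param recalls_path Input CSV when `simulate = FALSE`.
#' @param n_participants Cohort size for simulation.
#' @param participant_effect_sd Within-person latent correlation control.
#' @param seed Master seed: simulation uses `seed`, CV folds `seed + 1`.
#' @param method Rank-correlation method, `"spearman"` or `"kendall"`.
#' @param nlambda,lambda_min_ratio Penalty-grid parameters.
#' @param folds CV folds (default 10).
#' @param sign_specific Direction-specific edge matching in the
#'   comparison?
#' @param min_nodes Community size filter.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, recalls_path = NULL,
                            n_participants = 814L,
                            participant_effect_sd = 1, seed = 1L,
                            method = c("spearman", "kendall"),
                            nlambda = 30L, lambda_min_ratio = 0.01,
                            folds = 10L, sign_specific = TRUE,
                            min_nodes = 3L) {
  method <- match.arg(method)
  if (!simulate && is.null(recalls_path)) {
    abort("`recalls_path` is required when `simulate = FALSE`.")
  }
  structure(
    list(simulate = simulate, recalls_path = recalls_path,
         n_participants = as.integer(n_participants),
         participant_effect_sd = participant_effect_sd,
         seed = as.integer(seed), method = method,
         nlambda = as.integer(nlambda),
         lambda_min_ratio = lambda_min_ratio, folds = as.integer(folds),
         sign_specific = sign_specific, min_nodes = as.integer(min_nodes)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' @param config A [pipeline_config()].
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full dietary-network analysis
#'
#' Simulate or load recalls, build the four meal tables and the habitual
#' table, fit the copula graphical model to each (skeptic correlation,
#' tenfold cross-validated glasso, partial-correlation network), detect
#' link communities and centrality, and compare meal networks against the
#' habitual network. All artifacts are written under `out_dir` and listed
#' with MD5 checksums in `manifest.json`; runs are fully deterministic
#' given the config seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (config snapshot, per-stage
#'   timings, per-network summaries, file inventory with checksums) and
#'   `results` (in-memory fits, communities, report).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]

  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage \"%s\" failed: %s", name,
                    conditionMessage(e)))
    })
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  recalls <- stage("input", {
    if (config$simulate) {
      preset <- cohort_preset(n_participants = config$n_participants,
                              participant_effect_sd = config$participant_effect_sd,
                              seed = config$seed)
      rec <- generate_recalls(preset$cohort, preset$margins,
                              seed = config$seed)
      write_recalls(rec, file.path(out_dir, "recalls.csv"))
      rec
    } else {
      read_recalls(config$recalls_path)
    }
  })

  meals <- attr(recalls, "meals")
  tables <- stage("tables", {
    tabs <- lapply(setNames(meals, meals),
                   function(m) build_meal_table(recalls, m))
    tabs$habitual <- build_habitual_table(recalls)
    for (nm in names(tabs)) {
      write_intake_table(tabs[[nm]],
                         file.path(out_dir, paste0("table_", slug(nm), ".tsv")))
    }
    tabs
  })

  fits <- stage("networks", {
    lapply(setNames(names(tables), names(tables)), function(nm) {
      fit <- fit_dietary_network(tables[[nm]], method = config$method,
                                 k = config$folds, seed = config$seed + 1L,
                                 nlambda = config$nlambda,
                                 lambda_min_ratio = config$lambda_min_ratio)
      write_edge_list(fit$network,
                      file.path(out_dir, paste0("network_", slug(nm), ".tsv")))
      write_cv_json(fit$cv, file.path(out_dir, paste0("cv_", slug(nm), ".json")))
      fit
    })
  })

  communities <- stage("communities", {
    lapply(setNames(names(fits), names(fits)), function(nm) {
      net <- fits[[nm]]$network
      lc <- if (nrow(net$edges) >= 1L) {
        link_communities(net, min_nodes = config$min_nodes)
      }
      if (!is.null(lc)) {
        write_communities_json(lc, file.path(out_dir,
                                             paste0("communities_", slug(nm), ".json")))
        write_centrality_tsv(community_centrality(lc),
                             file.path(out_dir,
                                       paste0("centrality_", slug(nm), ".tsv")))
      }
      write_network_graphml(net,
                            file.path(out_dir, paste0("network_", slug(nm), ".graphml")),
                            communities = lc)
      lc
    })
  })

  report <- stage("compare", {
    meal_nets <- lapply(fits[meals], function(f) f$network)
    rep <- overlap_report(meal_nets, fits$habitual$network,
                          sign_specific = config$sign_specific)
    write_overlap_report(rep, file.path(out_dir, "comparison"))
    rep
  })

  summaries <- purrr::imap_dfr(fits, function(f, nm) {
    lc <- communities[[nm]]
    tibble(network = nm, n_nodes = nrow(f$network$nodes),
           n_edges = nrow(f$network$edges),
           n_networks = f$network$n_networks,
           lambda_opt = f$cv$lambda_opt,
           n_communities = if (is.null(lc)) 0L else nrow(lc$communities),
           n_central = if (is.null(lc)) 0L else
             sum(community_centrality(lc)$central))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mealnets")),
    config = unclass(config),
    timings = timings,
    networks = summaries,
    files = file_inventory(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(list(manifest = manifest,
                 results = list(recalls = recalls, tables = tables,
                                fits = fits, communities = communities,
                                report = report)))
}

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

file_inventory <- function(dir) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  tibble(file = files,
         md5 = unname(tools::md5sum(file.path(dir, files))))
}
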