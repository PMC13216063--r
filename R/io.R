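#' Read and write concept-set files
#'
#' The concept-set exchange format is UTF-8 delimited text with header
#' `category_id,dim_0,...,dim_{d_c-1}` and one row per category; values are
#' written in scientific notation with 17 significant digits so the round
#' trip is value-exact.
#'
#' @param concepts concept matrix with named rows.
#' @param path file path.
#' @return `write_conceptset` returns `path` invisibly; `read_conceptset`
#'   returns the concept matrix.
#' @export
write_conceptset <- function(concepts, path) {
  stopifnot(is.matrix(concepts), !is.null(rownames(concepts)))
  d <- ncol(concepts)
  header <- paste(c("category_id", paste0("dim_", seq_len(d) - 1L)),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(concepts)), function(i) {
    paste(c(rownames(concepts)[i],
            sprintf("%.17e", concepts[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_conceptset
#' @export
read_conceptset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty concept-set file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "category_id" ||
      !all(grepl("^dim_[0-9]+$", header[-1L]))) {
    stop("malformed concept-set header (line 1) in ", path, call. = FALSE)
  }
  d <- length(header) - 1L
  body <- lines[-1L]
  body <- body[nzchar(body)]
  out <- matrix(NA_real_, length(body), d)
  ids <- character(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) != d + 1L) {
      stop(sprintf("malformed concept-set row at line %d (%d fields, expected %d)",
                   i + 1L, length(parts), d + 1L), call. = FALSE)
    }
    ids[i] <- parts[1L]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric concept value at line %d", i + 1L),
           call. = FALSE)
    }
    out[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    stop("duplicate category ids in ", path, call. = FALSE)
  }
  rownames(out) <- ids
  out
}

#' Read and write RDM files
#'
#' Two delimited-text layouts: `"matrix"` (square, header row and first
#' column carry item labels) and `"long"` (`item_a,item_b,d`, upper
#' triangle only).
#'
#' @param rdm symmetric dissimilarity matrix with named rows/columns.
#' @param path file path.
#' @param format `"matrix"` or `"long"`.
#' @return `write_rdm` returns `path` invisibly; `read_rdm` returns the
#'   matrix.
#' @export
write_rdm <- function(rdm, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  rdm <- unclass(as.matrix(rdm))
  items <- rownames(rdm) %||% paste0("item_", seq_len(nrow(rdm)))
  if (format == "matrix") {
    header <- paste(c("item", items), collapse = ",")
    rows <- vapply(seq_len(nrow(rdm)), function(i) {
      paste(c(items[i], sprintf("%.17e", rdm[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(header, rows), path, useBytes = TRUE)
  } else {
    lines <- c("item_a,item_b,d")
    for (i in seq_len(nrow(rdm) - 1L)) {
      for (j in (i + 1L):ncol(rdm)) {
        lines <- c(lines, paste(items[i], items[j],
                                sprintf("%.17e", rdm[i, j]), sep = ","))
      }
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path, format = c("matrix", "long")) {
  format <- match.arg(format)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty RDM file: ", path, call. = FALSE)
  if (format == "matrix") {
    header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
    items <- header[-1L]
    n <- length(items)
    if (length(lines) - 1L != n) {
      stop(sprintf("RDM file has %d data rows but %d header items",
                   length(lines) - 1L, n), call. = FALSE)
    }
    m <- matrix(NA_real_, n, n, dimnames = list(items, items))
    for (i in seq_len(n)) {
      parts <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
      if (length(parts) != n + 1L) {
        stop(sprintf("truncated RDM row '%s' at line %d (%d fields, expected %d)",
                     parts[1L], i + 1L, length(parts), n + 1L),
             call. = FALSE)
      }
      m[i, ] <- as.numeric(parts[-1L])
    }
    if (max(abs(m - t(m))) > 1e-8) {
      stop("RDM in ", path, " is not symmetric", call. = FALSE)
    }
    m
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("item_a", "item_b", "d") %in% names(df))) {
      stop("long-format RDM needs columns item_a,item_b,d", call. = FALSE)
    }
    items <- sort(unique(c(df$item_a, df$item_b)))
    n <- length(items)
    m <- matrix(0, n, n, dimnames = list(items, items))
    for (r in seq_len(nrow(df))) {
      m[df$item_a[r], df$item_b[r]] <- df$d[r]
      m[df$item_b[r], df$item_a[r]] <- df$d[r]
    }
    m
  }
}

write_manifest <- function(dir, subcommand, args, seed) {
  cfg_files <- args[file.exists(args) & !dir.exists(args)]
  hashes <- if (length(cfg_files)) {
    as.list(tools::md5sum(cfg_files))
  } else list()
  manifest <- list(subcommand = subcommand,
                   args = as.list(args),
                   seed = seed,
                   package_version =
                     as.character(utils::packageVersion("catsnet")),
                   input_md5 = hashes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

cli_usage <- function() {
  paste(
    "usage: catsnet <subcommand> [options]",
    "subcommands:",
    "  simulate features|rdms|world --out DIR [--spec FILE] [--seed N]",
    "  train --config FILE --out DIR",
    "  evaluate --checkpoint FILE --world-seed N --out DIR",
    "  entropy --counts FILE",
    "  rdm --input FILE --metric pearson|cosine|euclidean --out FILE",
    "  cluster --input FILE --out FILE",
    "  cam --checkpoint FILE --concept-id ID --stack FILE --out FILE",
    "  communicate --rounds N --out DIR [--seed N]",
    "  rsa --model-rdm FILE --subject-rdms FILE[,FILE...] [--covariate-rdm FILE] --out FILE",
    sep = "\n")
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1L] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1L] + 1L]
}

#' Command-line entry point
#'
#' Dispatches the package's pipelines from a character argument vector
#' (e.g. `commandArgs(trailingOnly = TRUE)` from the thin wrapper script in
#' `inst/cli/catsnet`). Every artifact-producing run writes a
#' `manifest.json` (arguments, seed, package version, input checksums) next
#' to its outputs.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
cats_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  known_flags <- c("--spec", "--out", "--seed", "--config", "--checkpoint",
                   "--world-seed", "--counts", "--input", "--metric",
                   "--concept-id", "--stack", "--rounds", "--model-rdm",
                   "--subject-rdms", "--covariate-rdm")
  flags <- grep("^--", rest, value = TRUE)
  unknown <- setdiff(flags, known_flags)
  if (length(unknown)) {
    message("unknown flag(s): ", paste(unknown, collapse = ", "), "\n",
            cli_usage())
    return(invisible(2L))
  }
  seed <- as.integer(cli_opt(rest, "--seed", "1"))
  status <- tryCatch({
    switch(sub,
      simulate = cli_simulate(rest, seed),
      train = cli_train(rest, seed),
      evaluate = cli_evaluate(rest, seed),
      entropy = cli_entropy(rest),
      rdm = cli_rdm(rest),
      cluster = cli_cluster(rest),
      cam = cli_cam(rest),
      communicate = cli_communicate(rest, seed),
      rsa = cli_rsa(rest),
      {
        message("unknown subcommand: ", sub, "\n", cli_usage())
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status %||% 0L)
}

read_yaml_spec <- function(rest, default = list()) {
  spec_path <- cli_opt(rest, "--spec")
  if (is.null(spec_path)) return(default)
  utils::modifyList(default, yaml::read_yaml(spec_path))
}

cli_simulate <- function(rest, seed) {
  what <- rest[!grepl("^--", rest)]
  what <- setdiff(what, c())[1L]
  out <- cli_opt(rest, "--out")
  if (is.null(out) || is.na(what)) stop("simulate needs a target and --out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (what == "features") {
    spec <- read_yaml_spec(rest, list(n_classes = 8, feature_dim = 32,
                                      samples_per_class = 100))
    w <- generate_class_features(n_classes = spec$n_classes,
                                 feature_dim = spec$feature_dim,
                                 samples_per_class = spec$samples_per_class,
                                 seed = seed)
    for (cl in names(w$features_by_class)) {
      utils::write.csv(w$features_by_class[[cl]],
                       file.path(out, paste0("features_", cl, ".csv")),
                       row.names = FALSE)
    }
    write_rdm(w$rdm, file.path(out, "ground_truth_rdm.csv"))
  } else if (what == "rdms") {
    spec <- read_yaml_spec(rest, list(n_items = 12, n_subjects = 12,
                                      noise_sd = 0.2, n_model_instances = 8,
                                      instance_noise_sd = 0.1))
    ens <- generate_rdm_ensemble(n_items = spec$n_items,
                                 n_subjects = spec$n_subjects,
                                 noise_sd = spec$noise_sd,
                                 n_model_instances = spec$n_model_instances,
                                 instance_noise_sd = spec$instance_noise_sd,
                                 seed = seed)
    write_rdm(ens$signal, file.path(out, "signal_rdm.csv"))
    for (i in seq_along(ens$subjects)) {
      write_rdm(ens$subjects[[i]],
                file.path(out, sprintf("subject_%02d_rdm.csv", i)))
    }
    for (i in seq_along(ens$instances)) {
      write_rdm(ens$instances[[i]],
                file.path(out, sprintf("instance_%02d_rdm.csv", i)))
    }
  } else if (what == "world") {
    spec <- read_yaml_spec(rest, list(n_hyper = 2, classes_per_hyper = 4,
                                      feature_dim = 32,
                                      samples_per_class = 100))
    w <- make_hypercategory_world(n_hyper = spec$n_hyper,
                                  classes_per_hyper = spec$classes_per_hyper,
                                  feature_dim = spec$feature_dim,
                                  samples_per_class = spec$samples_per_class,
                                  seed = seed)
    for (cl in names(w$features_by_class)) {
      utils::write.csv(w$features_by_class[[cl]],
                       file.path(out, paste0("features_", cl, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(w$hyper_map, file.path(out, "hyper_map.csv"),
                     row.names = FALSE)
    write_rdm(w$rdm, file.path(out, "ground_truth_rdm.csv"))
  } else {
    stop("unknown simulate target: ", what)
  }
  write_manifest(out, paste("simulate", what), rest, seed)
  0L
}

## training config file schema: a YAML map with `world` (generator
## arguments) and `train` (cats_train_config arguments) blocks plus
## optional d_c / hidden.
cli_train <- function(rest, seed) {
  cfg_path <- cli_opt(rest, "--config")
  out <- cli_opt(rest, "--out")
  if (is.null(cfg_path) || is.null(out)) stop("train needs --config and --out")
  cfg <- yaml::read_yaml(cfg_path)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  world_args <- utils::modifyList(list(n_classes = 8, feature_dim = 32,
                                       samples_per_class = 200, seed = seed),
                                  cfg$world %||% list())
  world <- do.call(generate_class_features, world_args)
  train_args <- utils::modifyList(list(seed = seed), cfg$train %||% list())
  config <- do.call(cats_train_config, train_args)
  fit <- catsnet(world$features_by_class,
                 d_c = cfg$d_c %||% 8L,
                 hidden = unlist(cfg$hidden %||% c(16L, 16L)),
                 config = config)
  save_checkpoint(fit$network, file.path(out, "checkpoint.rds"),
                  concepts = fit$concepts)
  write_conceptset(fit$concepts, file.path(out, "concepts.csv"))
  utils::write.csv(fit$history, file.path(out, "metrics.csv"),
                   row.names = FALSE)
  write_manifest(out, "train", rest, config$seed)
  message(sprintf("holdout macro accuracy: %.4f", fit$eval$macro))
  0L
}

cli_evaluate <- function(rest, seed) {
  ckpt <- cli_opt(rest, "--checkpoint")
  out <- cli_opt(rest, "--out")
  wseed <- as.integer(cli_opt(rest, "--world-seed", seed))
  if (is.null(ckpt) || is.null(out)) {
    stop("evaluate needs --checkpoint and --out")
  }
  loaded <- load_checkpoint(ckpt)
  if (is.null(loaded$concepts)) stop("checkpoint carries no concept set")
  world <- generate_class_features(n_classes = nrow(loaded$concepts),
                                   feature_dim = loaded$net$dims_ts[1L],
                                   samples_per_class = 50L, seed = wseed)
  ev <- evaluate_concepts(loaded$net, loaded$concepts,
                          world$features_by_class, seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(class = names(ev$per_class),
                              accuracy = as.numeric(ev$per_class)),
                   file.path(out, "accuracy.csv"), row.names = FALSE)
  write_manifest(out, "evaluate", rest, seed)
  message(sprintf("macro accuracy: %.4f", ev$macro))
  0L
}

cli_entropy <- function(rest) {
  counts_path <- cli_opt(rest, "--counts")
  if (is.null(counts_path)) stop("entropy needs --counts")
  df <- utils::read.csv(counts_path)
  res <- functional_entropy(df[[ncol(df)]])
  message(sprintf("functional entropy: %.6f nats over %d classes",
                  res$e, length(res$p)))
  0L
}

cli_rdm <- function(rest) {
  input <- cli_opt(rest, "--input")
  out <- cli_opt(rest, "--out")
  metric <- cli_opt(rest, "--metric", "pearson")
  if (is.null(input) || is.null(out)) stop("rdm needs --input and --out")
  vecs <- read_conceptset(input)
  write_rdm(rdm_from_vectors(vecs, metric), out)
  0L
}

cli_cluster <- function(rest) {
  input <- cli_opt(rest, "--input")
  out <- cli_opt(rest, "--out")
  if (is.null(input) || is.null(out)) stop("cluster needs --input and --out")
  vecs <- read_conceptset(input)
  hc <- hcluster_concepts(vecs)$hclust
  utils::write.csv(data.frame(step = seq_len(nrow(hc$merge)),
                              left = hc$merge[, 1L], right = hc$merge[, 2L],
                              height = hc$height),
                   out, row.names = FALSE)
  0L
}

cli_cam <- function(rest) {
  ckpt <- cli_opt(rest, "--checkpoint")
  cid <- cli_opt(rest, "--concept-id")
  stack_path <- cli_opt(rest, "--stack")
  out <- cli_opt(rest, "--out")
  if (is.null(ckpt) || is.null(cid) || is.null(stack_path) || is.null(out)) {
    stop("cam needs --checkpoint, --concept-id, --stack and --out")
  }
  loaded <- load_checkpoint(ckpt)
  stack_spec <- jsonlite::read_json(stack_path, simplifyVector = TRUE)
  A <- array(as.numeric(stack_spec$values), dim = unlist(stack_spec$dim))
  cam <- cats_cam(loaded$net, loaded$concepts[cid, ], A)
  utils::write.table(cam$map, out, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  0L
}

cli_communicate <- function(rest, seed) {
  out <- cli_opt(rest, "--out")
  rounds <- as.integer(cli_opt(rest, "--rounds", "5"))
  if (is.null(out)) stop("communicate needs --out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- run_communication_rounds(n_rounds = rounds, seed = seed)
  utils::write.csv(res$rounds, file.path(out, "rounds.csv"),
                   row.names = FALSE)
  write_manifest(out, "communicate", rest, seed)
  message(sprintf("mean transfer accuracy over %d rounds: %.4f", rounds,
                  res$mean_transfer))
  0L
}

cli_rsa <- function(rest) {
  model_path <- cli_opt(rest, "--model-rdm")
  subj_paths <- cli_opt(rest, "--subject-rdms")
  cov_path <- cli_opt(rest, "--covariate-rdm")
  out <- cli_opt(rest, "--out")
  if (is.null(model_path) || is.null(subj_paths) || is.null(out)) {
    stop("rsa needs --model-rdm, --subject-rdms and --out")
  }
  model <- read_rdm(model_path)
  subjects <- lapply(strsplit(subj_paths, ",")[[1L]], read_rdm)
  covariate <- if (!is.null(cov_path)) read_rdm(cov_path)
  rho <- vapply(subjects, function(s) {
    if (is.null(covariate)) spearman_rdm(model, s) else
      partial_spearman_rdm(model, s, covariate)
  }, numeric(1))
  z <- fisher_z(rho)
  gt <- group_level_tests(z, baseline = 0, tails = 1L)
  utils::write.csv(data.frame(subject = seq_along(rho), rho = rho, z = z),
                   out, row.names = FALSE)
  message(sprintf("mean rho = %.4f, t(%d) = %.3f, one-tailed p = %.3g",
                  mean(rho), gt$df, gt$t, gt$p))
  0L
}
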