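#' Read a delimited data matrix with feature identifiers
#'
#' Reads a CSV or TSV matrix (delimiter inferred from the extension, or
#' set explicitly). By default features are in rows with ids in the first
#' column and sample names in the header; `orientation =
#' "features_in_columns"` reads the transpose (ids from the header).
#' Missing values are rejected — imputation is a preprocessing step for
#' the user, as is filtering zero-variance features.
#'
#' @param path File path.
#' @param orientation `"features_in_rows"` (default) or
#'   `"features_in_columns"`.
#' @param sep Field separator; default inferred (`","` for `.csv`,
#'   otherwise tab).
#' @return List with `matrix` (samples x features, feature ids as column
#'   names) and `feature_ids`.
#' @export
read_matrix <- function(path, orientation = c("features_in_rows",
                                              "features_in_columns"),
                        sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (orientation == "features_in_rows") {
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    m <- t(m)
    colnames(m) <- ids
  } else {
    first_is_id <- !is.numeric(df[[1]])
    if (first_is_id) {
      rownames(df) <- df[[1]]
      df <- df[, -1, drop = FALSE]
    }
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    ids <- colnames(m)
  }
  if (anyDuplicated(ids))
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value in ", path, " (feature ", colnames(m)[bad[2]],
         "); impute upstream before running this tool")
  }
  list(matrix = m, feature_ids = ids)
}

#' Write a data matrix in the tool's delimited format
#'
#' Features in rows, ids in the first column, full float precision
#' (17 significant digits, so write/read round-trips are lossless).
#'
#' @param m Samples x features numeric matrix with feature-id column
#'   names.
#' @param path Output path (`.csv` uses commas, otherwise tabs).
#' @export
write_matrix <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature_id = colnames(m),
                   t(m), check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id",
                    rownames(m) %||% paste0("sample_", seq_len(nrow(m))))
  for (k in 2:ncol(df)) df[[k]] <- sprintf("%.17g", df[[k]])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a two-column layer annotation TSV
#'
#' @param path TSV with columns `feature_id` and `layer` (header
#'   required).
#' @return A [layer_annotation()].
#' @export
read_layers <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("feature_id", "layer") %in% colnames(df)))
    stop("layer file needs columns feature_id and layer")
  layer_annotation(df$feature_id, df$layer)
}

#' @rdname read_layers
#' @param annotation A [layer_annotation()].
#' @export
write_layers <- function(annotation, path) {
  write.table(as.data.frame(annotation)[, c("feature_id", "layer")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write and read network edge lists
#'
#' Edge lists are TSVs with columns `node_a`, `node_b`, `condition`
#' (`common`, `cond1` or `cond2`) and `weight` (17 significant digits;
#' common edges carry the mean of the two conditions' weights).
#'
#' @param networks A `ddn_networks`.
#' @param path Output path.
#' @export
write_edge_list <- function(networks, path) {
  common <- networks$common_edges
  df <- rbind(
    if (nrow(common)) data.frame(node_a = common$node_a,
                                 node_b = common$node_b,
                                 condition = "common",
                                 weight = (common$weight1 +
                                             common$weight2) / 2,
                                 stringsAsFactors = FALSE),
    networks$differential_edges[, c("node_a", "node_b", "condition",
                                    "weight")])
  if (is.null(df))
    df <- data.frame(node_a = character(0), node_b = character(0),
                     condition = character(0), weight = numeric(0))
  df$weight <- sprintf("%.17g", df$weight)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_edge_list
#' @return `read_edge_list()` returns the data frame with numeric
#'   weights.
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "numeric"))
  df
}

#' Export a simulated scenario to plain-text files
#'
#' Writes the truth edge lists (3-column TSV: `node_a`, `node_b`,
#' `membership` in template/cond1/cond2), the layer annotation, both
#' sample matrices, and a YAML replay config holding the generator
#' parameters and seed.
#'
#' @param scenario A `ddn_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- scenario$annotation$feature_id
  lab <- function(e, what) if (nrow(e) == 0)
    data.frame(node_a = character(0), node_b = character(0),
               membership = character(0))
  else data.frame(node_a = ids[e[, 1]], node_b = ids[e[, 2]],
                  membership = what, stringsAsFactors = FALSE)
  edges <- rbind(lab(scenario$template_edges, "template"),
                 lab(scenario$cond1_edges, "cond1"),
                 lab(scenario$cond2_edges, "cond2"))
  files <- file.path(dir, c("truth_edges.tsv", "layers.tsv",
                            "samples_cond1.csv", "samples_cond2.csv",
                            "scenario.yaml"))
  write.table(edges, files[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_layers(scenario$annotation, files[2])
  write_matrix(scenario$samples1, files[3])
  write_matrix(scenario$samples2, files[4])
  yaml::write_yaml(c(scenario$params,
                     list(seed = scenario$seed)), files[5])
  invisible(files)
}

#' Read a scenario replay config
#'
#' @param path YAML file with the [simulate_scenario()] parameters.
#' @return The regenerated `ddn_scenario` (exact replay from the stored
#'   seed).
#' @export
replay_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$n_per_layer <- unlist(cfg$n_per_layer)
  cfg$weight_range <- unlist(cfg$weight_range)
  do.call(simulate_scenario, cfg)
}

#' Read a constraints configuration file
#'
#' YAML schema:
#' \preformatted{
#' default_lambda1: 0.2        # scalar penalty defaults
#' default_lambda2: 0.05
#' rules:                      # layer-pair interaction rules, in order
#'   - {source: TF_protein, target: mRNA, directed: true, allowed: true}
#' edge_overrides:             # per-edge overrides (highest precedence)
#'   - {from: TP53, to: MDM2, directed: true, allowed: true}
#' lambda1_rules:              # per layer-pair penalties
#'   - {node_layer: mRNA, predictor_layer: TF_protein, value: 0.1}
#' lambda2_rules: []
#' }
#'
#' @param path YAML file.
#' @param annotation A [layer_annotation()] naming the features/layers.
#' @return A [ddn_spec] built via [build_spec()].
#' @export
read_constraints_config <- function(path, annotation) {
  cfg <- yaml::read_yaml(path)
  tab <- function(x, cols) {
    if (is.null(x) || length(x) == 0) return(NULL)
    do.call(rbind, lapply(x, function(row)
      as.data.frame(row[cols], stringsAsFactors = FALSE)))
  }
  rules <- tab(cfg$rules, c("source", "target", "directed", "allowed"))
  if (!is.null(rules))
    colnames(rules) <- c("source_layer", "target_layer", "directed",
                         "allowed")
  build_spec(annotation,
             rules = rules,
             edge_overrides = tab(cfg$edge_overrides,
                                  c("from", "to", "directed", "allowed")),
             lambda1_rules = tab(cfg$lambda1_rules,
                                 c("node_layer", "predictor_layer",
                                   "value")),
             lambda2_rules = tab(cfg$lambda2_rules,
                                 c("node_layer", "predictor_layer",
                                   "value")),
             default_lambda1 = cfg$default_lambda1 %||% 0,
             default_lambda2 = cfg$default_lambda2 %||% 0)
}

#' Write a run manifest
#'
#' Records inputs, seed, chosen hyperparameters, package version and
#' timestamps of a run as JSON, so a rerun from the same manifest inputs
#' reproduces identical outputs.
#'
#' @param path Output JSON path.
#' @param inputs Named list of input file paths.
#' @param seed Integer seed of the run.
#' @param hyperparameters Named list (e.g. lambda1/lambda2).
#' @param outputs Named list of output file paths.
#' @param extra Optional named list merged into the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, inputs = list(), seed = NULL,
                           hyperparameters = list(), outputs = list(),
                           extra = list()) {
  manifest <- c(list(
    tool = "ddnet",
    version = as.character(utils::packageVersion("ddnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    hyperparameters = hyperparameters,
    outputs = outputs), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
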