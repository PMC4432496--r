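# Orchestration: run configuration, staged subcommands, run manifests.

#' Run configuration
#'
#' Bundles every tunable of the pipeline stages so a run is a pure
#' function of (inputs, config, seed). Round-trips through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param library_path Path to an RU library FASTA (`NULL` uses the
#'   packaged library).
#' @param w_min,w_max,tau,identity_min Segmentation settings, see
#'   [seg_params()].
#' @param theta Conserved-array support threshold.
#' @param mh_min,nahr_min,slippage_window,relaxed_identity Mechanism
#'   thresholds, see [mechanism_config()].
#' @param seed Integer seed for stages that draw random numbers.
#' @param out_dir Output directory.
#' @param log_level One of `"quiet"`, `"info"`.
#' @return A list of class `vntr_run_config`.
#' @export
vntr_run_config <- function(library_path = NULL, w_min = 25L, w_max = 60L,
                            tau = 2, identity_min = 0.75, theta = 0.7,
                            mh_min = 5L, nahr_min = 34L,
                            slippage_window = 200L, relaxed_identity = 0.9,
                            seed = 1L, out_dir = ".",
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(library_path = library_path, w_min = as.integer(w_min),
              w_max = as.integer(w_max), tau = tau,
              identity_min = identity_min, theta = theta,
              mh_min = as.integer(mh_min), nahr_min = as.integer(nahr_min),
              slippage_window = as.integer(slippage_window),
              relaxed_identity = relaxed_identity, seed = as.integer(seed),
              out_dir = out_dir, log_level = log_level)
  # delegate range validation to the component constructors
  seg_params(cfg$w_min, cfg$w_max, cfg$tau, cfg$identity_min)
  mechanism_config(cfg$mh_min, cfg$nahr_min, cfg$slippage_window,
                   cfg$relaxed_identity)
  stopifnot(theta > 0, theta <= 1)
  structure(cfg, class = "vntr_run_config")
}

#' @rdname vntr_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(vntr_run_config, x)
}

#' @rdname vntr_run_config
#' @param config A `vntr_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_seg_params <- function(cfg) {
  seg_params(cfg$w_min, cfg$w_max, cfg$tau, cfg$identity_min)
}

config_mech <- function(cfg) {
  mechanism_config(cfg$mh_min, cfg$nahr_min, cfg$slippage_window,
                   cfg$relaxed_identity)
}

config_library <- function(cfg) {
  if (is.null(cfg$library_path)) vntr_ru_library() else
    read_ru_library(cfg$library_path)
}

log_info <- function(cfg, ...) {
  if (cfg$log_level != "quiet") message(...)
}

# write a file atomically: assemble under a temp name, then rename
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  path
}

run_manifest <- function(cfg, subcommand, inputs, outputs) {
  list(
    subcommand = subcommand,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    package_version = as.character(utils::packageVersion("vntrscheme")),
    r_version = as.character(getRversion())
  )
}

#' Run a pipeline stage
#'
#' Executes one stage over file inputs and writes its artifacts plus a
#' machine-readable run manifest (inputs, full config and its hash,
#' versions) to the configured output directory. Outputs are written
#' atomically. Stages: `tokenize` (elements FASTA to schema TSV and code
#' strings), `discover` (units FASTA to cluster/consensus TSV), `arrays`
#' (elements FASTA to per-subfamily conserved arrays and motifs, JSON and
#' text), `compare` (two-record pair FASTA to event JSON-lines and TSV),
#' `simulate` (grammar file to elements FASTA and truth JSON-lines).
#'
#' @param subcommand One of `"tokenize"`, `"discover"`, `"arrays"`,
#'   `"compare"`, `"simulate"`.
#' @param config A [vntr_run_config()].
#' @param inputs Character vector of input paths (one per stage; `compare`
#'   also accepts a pairs manifest TSV with columns `pair_id`, `path_a`,
#'   `path_b`).
#' @param n For `simulate`: number of elements to generate.
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_pipeline <- function(subcommand = c("tokenize", "discover", "arrays",
                                        "compare", "simulate"),
                         config = vntr_run_config(), inputs, n = 10) {
  subcommand <- match.arg(subcommand)
  if (subcommand != "simulate") {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) {
      abort(paste0("input not found: ", paste(missing, collapse = ", ")))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- config_library(config)
  p <- config_seg_params(config)
  mech <- config_mech(config)
  outp <- function(name) file.path(config$out_dir, name)
  outputs <- character()

  if (subcommand == "tokenize") {
    elements <- read_vntr_fasta(inputs[1])
    log_info(config, "tokenizing ", nrow(elements), " elements")
    sch <- segment_vntr(elements, lib, p)
    outputs <- c(schema = outp("schema.tsv"),
                 codes = outp("schema.tsv.codes.tsv"))
    atomic_write(outputs[["schema"]], function(f) {
      utils::write.table(as_tibble(sch), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    atomic_write(outputs[["codes"]], function(f) {
      utils::write.table(code_strings(sch), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  } else if (subcommand == "discover") {
    units <- read_vntr_fasta(inputs[1])
    cl <- discover_units(tibble(unit = units$sequence))
    outputs <- c(clusters = outp("clusters.tsv"))
    atomic_write(outputs[["clusters"]], function(f) {
      flat <- as_tibble(cl) |> select(-"members")
      utils::write.table(flat, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  } else if (subcommand == "arrays") {
    elements <- read_vntr_fasta(inputs[1])
    sch <- segment_vntr(elements, lib, p)
    tb <- as_tibble(sch)
    res <- list()
    for (sf in unique(tb$subfamily)) {
      sub <- structure(tb[tb$subfamily == sf, ],
                       sequences = attr(sch, "sequences"))
      ac <- consensus_arrays(sub, theta = config$theta)
      mot <- mine_internal_arrays(sub, theta = config$theta)
      res[[sf]] <- list(
        subfamily = sf,
        n_elements = ac$n_elements,
        prefix = ac$prefix, prefix_code = render_array(ac, "prefix"),
        suffix = ac$suffix, suffix_code = render_array(ac, "suffix"),
        alt_prefix = ac$alt_prefix,
        motifs = as_tibble(mot) |> select(-"tokens")
      )
    }
    outputs <- c(arrays = outp("arrays.json"), text = outp("arrays.txt"))
    atomic_write(outputs[["arrays"]], function(f) {
      jsonlite::write_json(res, f, dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE)
    })
    atomic_write(outputs[["text"]], function(f) {
      writeLines(map_chr(res, function(r) {
        sprintf("%s\t5' %s\t3' %s\t%s", r$subfamily, r$prefix_code,
                r$suffix_code, paste(r$motifs$motif, collapse = ","))
      }), f)
    })
  } else if (subcommand == "compare") {
    pairs <- if (grepl("\\.tsv$", inputs[1])) {
      utils::read.delim(inputs[1], stringsAsFactors = FALSE)
    } else {
      data.frame(pair_id = basename(inputs[1]), path_a = inputs[1],
                 path_b = NA_character_)
    }
    all_ev <- list()
    for (i in seq_len(nrow(pairs))) {
      pp <- if (is.na(pairs$path_b[i])) {
        read_vntr_fasta(pairs$path_a[i])
      } else {
        bind_rows(read_vntr_fasta(pairs$path_a[i])[1, ],
                  read_vntr_fasta(pairs$path_b[i])[1, ])
      }
      ev <- compare_orthologs(pp, lib, p, mech)
      all_ev[[i]] <- as_tibble(ev)
    }
    ev <- bind_rows(all_ev)
    outputs <- c(events = outp("events.jsonl"), summary = outp("events.tsv"))
    atomic_write(outputs[["events"]], function(f) {
      if (nrow(ev)) {
        class(ev) <- c("vntr_events", class(tibble()))
        write_events(ev, f)
      } else {
        writeLines(character(), f)
      }
    })
    atomic_write(outputs[["summary"]], function(f) {
      flat <- if (nrow(ev)) {
        ev |> mutate(labels = map_chr(.data$labels, paste, collapse = ",")) |>
          select("pair_id", "carrier", "start", "end", "length",
                 "mh_exact_left", "mh_exact_right", "mh_relaxed", "labels")
      } else {
        tibble(pair_id = character(), carrier = character(),
               start = integer(), end = integer(), length = integer(),
               mh_exact_left = integer(), mh_exact_right = integer(),
               mh_relaxed = integer(), labels = character())
      }
      utils::write.table(flat, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  } else if (subcommand == "simulate") {
    g <- if (file.exists(inputs[1])) read_grammar(inputs[1]) else
      packaged_grammars(inputs[1])
    sim <- generate_subfamily_set(g, n = n, seed = config$seed, lib = lib)
    outputs <- c(fasta = outp(paste0(g$name, ".fasta")),
                 truth = outp(paste0(g$name, ".truth.jsonl")))
    atomic_write(outputs[["fasta"]], function(f) {
      write_vntr_fasta(sim$elements, f)
    })
    atomic_write(outputs[["truth"]], function(f) {
      lines <- map_chr(seq_len(nrow(sim$truth)), function(i) {
        jsonlite::toJSON(list(
          element_id = sim$truth$element_id[i],
          generating_tokens = sim$truth$generating_tokens[[i]],
          clean_sequence = sim$truth$clean_sequence[i],
          mutations = sim$truth$mutations[[i]]
        ), auto_unbox = TRUE, dataframe = "rows")
      })
      writeLines(lines, f)
    })
  }

  manifest_path <- outp(paste0(subcommand, ".manifest.json"))
  atomic_write(manifest_path, function(f) {
    jsonlite::write_json(run_manifest(config, subcommand, inputs, outputs),
                         f, auto_unbox = TRUE, pretty = TRUE, null = "null")
  })
  invisible(c(outputs, manifest = manifest_path))
}
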