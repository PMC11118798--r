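# internal: canonical edge label
edge_label <- function(source, target) paste0(source, "->", target)

#' Construct a region specification
#'
#' A region is an anatomical structure of the brainstem, diencephalon or
#' spinal cord that enters the network model, subdivided into
#' `n_subregions` near-equal-volume clusters (one of which is selected
#' during fitting).
#'
#' @param name full anatomical name.
#' @param abbrev short unique code (e.g. `"C6RD"`, `"PAG"`).
#' @param n_subregions number of k-means sub-regions (default 5).
#' @return a `region_spec` list.
#' @export
region_spec <- function(name, abbrev, n_subregions = 5L) {
  stopifnot(is.character(name), is.character(abbrev), nchar(abbrev) > 0)
  n_subregions <- as.integer(n_subregions)
  if (is.na(n_subregions) || n_subregions < 1L)
    stop("n_subregions must be a positive integer", call. = FALSE)
  structure(list(name = name, abbrev = abbrev, n_subregions = n_subregions),
            class = "region_spec")
}

#' Construct and validate a latent-input network model
#'
#' The network model is a directed graph over anatomical regions, plus
#' latent ("intrinsic") inputs entering from outside the network (e.g.
#' cortical drive).  Each inter-region connection carries a signed
#' connectivity (DB) weight when fitted; each latent targets one or more
#' regions through latent links.
#'
#' @param regions list of [region_spec()] objects (or a data.frame with
#'   columns `name`, `abbrev`, `n_subregions`).
#' @param connections data.frame with columns `source`, `target`
#'   (region abbrevs) and optionally `provenance`.
#' @param latents list of `list(name=, targets=)` entries.
#' @return an object of class `sapm_network`.
#' @export
network_model <- function(regions, connections, latents = list()) {
  if (is.data.frame(regions)) {
    reg_df <- regions
    if (is.null(reg_df$n_subregions)) reg_df$n_subregions <- 5L
  } else {
    reg_df <- do.call(rbind, lapply(regions, function(r)
      data.frame(name = r$name, abbrev = r$abbrev,
                 n_subregions = r$n_subregions,
                 stringsAsFactors = FALSE)))
  }
  reg_df$n_subregions <- as.integer(reg_df$n_subregions)
  if (anyDuplicated(reg_df$abbrev))
    stop("duplicate region abbrev: ",
         paste(unique(reg_df$abbrev[duplicated(reg_df$abbrev)]), collapse = ", "),
         call. = FALSE)
  if (any(reg_df$n_subregions < 1L))
    stop("n_subregions must be >= 1", call. = FALSE)

  if (is.null(connections) || nrow(as.data.frame(connections)) == 0L) {
    con_df <- data.frame(source = character(), target = character(),
                         provenance = character(), stringsAsFactors = FALSE)
  } else {
    con_df <- as.data.frame(connections, stringsAsFactors = FALSE)
    if (is.null(con_df$provenance)) con_df$provenance <- "unspecified"
  }
  latents <- lapply(latents, function(l) {
    stopifnot(!is.null(l$name), !is.null(l$targets))
    list(name = as.character(l$name), targets = as.character(unlist(l$targets)))
  })

  net <- structure(list(regions = reg_df, connections = con_df,
                        latents = latents), class = "sapm_network")
  issues <- validate_network(net)
  if (length(issues)) stop("invalid network model:\n  ",
                           paste(issues, collapse = "\n  "), call. = FALSE)
  net
}

#' Validate a network model
#'
#' @param net a `sapm_network`.
#' @return character vector of issues (empty if valid).
#' @export
validate_network <- function(net) {
  issues <- character()
  abbrevs <- net$regions$abbrev
  con <- net$connections
  if (nrow(con)) {
    bad <- !(con$source %in% abbrevs)
    if (any(bad)) issues <- c(issues, paste0(
      "connection ", edge_label(con$source[bad], con$target[bad]),
      ": unknown source region '", con$source[bad], "'"))
    bad <- !(con$target %in% abbrevs)
    if (any(bad)) issues <- c(issues, paste0(
      "connection ", edge_label(con$source[bad], con$target[bad]),
      ": unknown target region '", con$target[bad], "'"))
    self <- con$source == con$target
    if (any(self)) issues <- c(issues, paste0(
      "self-loop not permitted: ", edge_label(con$source[self], con$target[self])))
    lab <- edge_label(con$source, con$target)
    if (anyDuplicated(lab)) issues <- c(issues, paste0(
      "duplicate connection: ", unique(lab[duplicated(lab)])))
  }
  for (l in net$latents) {
    if (!length(l$targets))
      issues <- c(issues, paste0("latent '", l$name, "' has no targets"))
    bad <- setdiff(l$targets, abbrevs)
    if (length(bad)) issues <- c(issues, paste0(
      "latent '", l$name, "' targets unknown region '", bad, "'"))
  }
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  if (anyDuplicated(lnames))
    issues <- c(issues, paste0("duplicate latent name: ",
                               unique(lnames[duplicated(lnames)])))
  issues
}

#' @export
print.sapm_network <- function(x, ...) {
  cat("sapm_network:", nrow(x$regions), "regions,",
      nrow(x$connections), "inter-region connections,",
      length(x$latents), "latent inputs",
      sprintf("(%d total connections)\n", connection_count(x, TRUE)))
  cat("  regions:", paste(x$regions$abbrev, collapse = ", "), "\n")
  invisible(x)
}

#' Count directed connections in a network
#'
#' @param net a `sapm_network`.
#' @param include_latent if `TRUE`, count inter-region edges plus one per
#'   (latent, target) link; if `FALSE`, inter-region edges only (the
#'   count used for Bonferroni correction).
#' @return non-negative integer.
#' @export
connection_count <- function(net, include_latent = TRUE) {
  n <- nrow(net$connections)
  if (include_latent)
    n <- n + sum(vapply(net$latents, function(l) length(l$targets), integer(1)))
  as.integer(n)
}

#' Labels of all connections in deterministic order
#'
#' Inter-region edges in declaration order, then latent links in latent
#' declaration order.  Labels have the form `"SRC->TGT"`.
#'
#' @param net a `sapm_network`.
#' @param include_latent include latent links.
#' @return character vector.
#' @export
connection_labels <- function(net, include_latent = TRUE) {
  lab <- if (nrow(net$connections))
    edge_label(net$connections$source, net$connections$target) else character()
  if (include_latent)
    for (l in net$latents) lab <- c(lab, edge_label(l$name, l$targets))
  lab
}

#' Binary adjacency mask
#'
#' Rows are sources (regions in declaration order, then latents), columns
#' are target regions; entry 1 iff the directed connection exists.
#'
#' @param net a `sapm_network`.
#' @return binary matrix with dimnames.
#' @export
adjacency_mask <- function(net) {
  abbrevs <- net$regions$abbrev
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  m <- matrix(0L, nrow = length(abbrevs) + length(lnames), ncol = length(abbrevs),
              dimnames = list(c(abbrevs, lnames), abbrevs))
  con <- net$connections
  if (nrow(con)) m[cbind(con$source, con$target)] <- 1L
  for (l in net$latents) m[cbind(l$name, l$targets)] <- 1L
  m
}

#' Load a network model from a YAML or JSON spec file
#'
#' The spec dialect has keys `regions` (list of `{name, abbrev,
#' n_subregions}`), `connections` (list of `{source, target,
#' provenance}`), and `latents` (list of `{name, targets}`).
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return a validated `sapm_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network spec file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  regions <- lapply(raw$regions, function(r)
    region_spec(r$name, r$abbrev,
                if (is.null(r$n_subregions)) 5L else r$n_subregions))
  con <- if (length(raw$connections)) do.call(rbind, lapply(raw$connections,
    function(e) data.frame(source = e$source, target = e$target,
                           provenance = if (is.null(e$provenance)) "unspecified"
                                        else e$provenance,
                           stringsAsFactors = FALSE))) else NULL
  latents <- lapply(raw$latents, function(l) list(name = l$name, targets = l$targets))
  network_model(regions, con, latents)
}

#' Save a network model to YAML or JSON
#'
#' Round-trips losslessly through [load_network()].
#'
#' @param net a `sapm_network`.
#' @param path output path (`.json` for JSON, else YAML).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  obj <- list(
    regions = lapply(seq_len(nrow(net$regions)), function(i)
      list(name = net$regions$name[i], abbrev = net$regions$abbrev[i],
           n_subregions = net$regions$n_subregions[i])),
    connections = lapply(seq_len(nrow(net$connections)), function(i)
      list(source = net$connections$source[i],
           target = net$connections$target[i],
           provenance = net$connections$provenance[i])),
    latents = lapply(net$latents, function(l)
      list(name = l$name, targets = as.list(l$targets))))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' The packaged descending pain-regulation network
#'
#' Ten regions of the brainstem, diencephalon and cervical spinal cord
#' (C6RD, DRt, Hypothalamus, LC, NGc, NRM, NTS, PAG, PBN, Thalamus), 32
#' directed inter-region connections and 3 latent inputs (35 connections
#' in total).  Edges named in the source literature's text and
#' connectivity tables are tagged `provenance: text`; the remainder are
#' plausible descending-pain-modulation pathways tagged
#' `provenance: fixture` (the published figure is not machine-readable,
#' so the full 32-edge set is a declared fixture).
#'
#' @return a `sapm_network`.
#' @export
default_network <- function() {
  load_network(system.file("networks", "fm_brainstem_cord.yaml",
                           package = "sapmnet", mustWork = TRUE))
}
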