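# Readers and writers for the interchange formats. All writers are
# deterministic: stable row ordering and floats formatted with 12
# significant digits.

fmt_num <- function(x) {
  ifelse(is.finite(x), formatC(x, digits = 12, format = "g"),
         ifelse(is.infinite(x) & x > 0, "inf", "-inf"))
}

#' Read a single-layer network from TSV or GML
#'
#' The TSV format is `src<TAB>dst[<TAB>weight]`, one edge per line, weight
#' defaulting to 1; node names are arbitrary strings and duplicate edges
#' are merged by summing weights. GML files are read through igraph; node
#' `label` attributes (falling back to `id`) become external labels and an
#' edge `weight` attribute is honored.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"gml"`.
#' @return a `champ_network` with external labels preserved.
#' @export
read_network <- function(path, format = c("auto", "tsv", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "tsv"
  if (format == "gml") {
    g <- igraph::read_graph(path, format = "gml")
    ed <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(ed) == 0L) stop("no edges")
    w <- if ("weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight else rep(1, nrow(ed))
    labs <- if ("label" %in% igraph::vertex_attr_names(g)) {
      as.character(igraph::V(g)$label)
    } else if ("id" %in% igraph::vertex_attr_names(g)) {
      as.character(igraph::V(g)$id)
    } else as.character(seq_len(igraph::vcount(g)))
    return(champ_network(data.frame(src = ed[, 1], dst = ed[, 2],
                                    weight = w),
                         n_nodes = igraph::vcount(g), labels = labs))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no edges")
  src <- character(length(lines)); dst <- character(length(lines))
  w <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("malformed edge line %d: %s", i, lines[i]))
    src[i] <- parts[1]; dst[i] <- parts[2]
    if (length(parts) >= 3L) {
      wi <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(wi))
        stop(sprintf("non-numeric weight on line %d: %s", i, parts[3]))
      w[i] <- wi
    } else w[i] <- 1.0
  }
  labs <- unique(c(src, dst))
  champ_network(data.frame(src = match(src, labs), dst = match(dst, labs),
                           weight = w),
                n_nodes = length(labs), labels = labs)
}

#' Read a multilayer network from TSV tables
#'
#' `nodes_path` is a `node<TAB>layer` table enumerating the state nodes
#' (one row per node-layer pair). `intra_path` has columns
#' `src<TAB>dst<TAB>weight<TAB>layer` (both endpoints in that layer).
#' `inter_path` has columns
#' `src<TAB>src_layer<TAB>dst<TAB>dst_layer[<TAB>weight]`; the layer
#' columns are needed because a state node is identified by a (node, layer)
#' pair.
#'
#' @param intra_path,inter_path,nodes_path file paths; `inter_path` may be
#'   `NULL` for uncoupled layers.
#' @return a `champ_multilayer` with labels `node@layer`.
#' @export
read_multilayer <- function(intra_path, inter_path, nodes_path) {
  nodes <- utils::read.table(nodes_path, sep = "\t",
                             col.names = c("node", "layer"),
                             colClasses = c("character", "integer"))
  key <- paste0(nodes$node, "@", nodes$layer)
  state_of <- function(node, layer) {
    idx <- match(paste0(node, "@", layer), key)
    if (anyNA(idx)) stop("edge refers to unknown state node")
    idx
  }
  intra <- utils::read.table(intra_path, sep = "\t",
                             col.names = c("src", "dst", "weight", "layer"),
                             colClasses = c("character", "character",
                                            "numeric", "integer"))
  intra_e <- data.frame(src = state_of(intra$src, intra$layer),
                        dst = state_of(intra$dst, intra$layer),
                        weight = intra$weight)
  inter_e <- data.frame(src = integer(0), dst = integer(0),
                        weight = numeric(0))
  if (!is.null(inter_path) && file.exists(inter_path) &&
      length(readLines(inter_path)) > 0) {
    inter <- utils::read.table(inter_path, sep = "\t", fill = TRUE,
                               col.names = c("src", "src_layer", "dst",
                                             "dst_layer", "weight"),
                               colClasses = c("character", "integer",
                                              "character", "integer",
                                              "numeric"))
    inter$weight[is.na(inter$weight)] <- 1.0
    inter_e <- data.frame(src = state_of(inter$src, inter$src_layer),
                          dst = state_of(inter$dst, inter$dst_layer),
                          weight = inter$weight)
  }
  champ_multilayer(intra_e, inter_e, nodes$layer, labels = key)
}

#' Write / read a partition ensemble as CSV
#'
#' One row per partition, one column per node, header row of node labels;
#' entries are canonical community labels. Round-trips canonical
#' partitions exactly.
#'
#' @param partitions matrix of memberships (one row per partition) or list.
#' @param path file path.
#' @param labels node labels for the header (default from the matrix
#'   columns or `V1..Vn`).
#' @export
write_ensemble <- function(partitions, path, labels = NULL) {
  if (is.list(partitions)) partitions <- do.call(rbind, partitions)
  n <- ncol(partitions)
  if (is.null(labels)) labels <- colnames(partitions)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = ","), con)
  if (nrow(partitions) > 0)
    writeLines(apply(partitions, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_ensemble
#' @param net optional `champ_network` (or `champ_multilayer`); when given,
#'   the file's node columns are matched against the network's labels and
#'   reordered to the network's node order.
#' @return `read_ensemble`: matrix of canonical memberships (possibly 0
#'   rows), with node labels as column names.
#' @export
read_ensemble <- function(path, net = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  if (!length(lines)) stop("empty ensemble file")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- lines[-1][nzchar(lines[-1])]
  reorder <- seq_along(header)
  if (!is.null(net)) {
    reorder <- match(net$labels, header)
    if (anyNA(reorder)) stop("unknown node column in ensemble")
  }
  if (!length(body)) {
    m <- matrix(integer(0), nrow = 0, ncol = length(header))
    colnames(m) <- header[reorder]
    return(m)
  }
  rows <- lapply(seq_along(body), function(i) {
    vals <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(vals) != length(header) || any(!nzchar(vals)))
      stop(sprintf("malformed ensemble row %d", i + 1L))
    canonicalize_membership(vals[reorder])
  })
  m <- do.call(rbind, lapply(rows, as.integer))
  colnames(m) <- header[reorder]
  m
}

#' Write / read a coefficient table CSV
#'
#' Columns: `partition_id,a_hat,p_hat,c_hat,n_communities,
#' n_communities_min5`.
#'
#' @param coeffs coefficient data frame.
#' @param path file path.
#' @export
write_coefficients <- function(coeffs, path) {
  cols <- c("partition_id", "a_hat", "p_hat", "c_hat", "n_communities",
            "n_communities_min5")
  for (cl in setdiff(cols, names(coeffs))) coeffs[[cl]] <- NA
  df <- coeffs[, cols]
  lines <- c(paste(cols, collapse = ","),
             apply(cbind(df$partition_id, fmt_num(df$a_hat),
                         fmt_num(df$p_hat), fmt_num(df$c_hat),
                         df$n_communities, df$n_communities_min5),
                   1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  utils::read.csv(path)
}

#' Write a 1-D domain table CSV
#'
#' Columns: `partition_id,gamma_lo,gamma_hi,a_hat,p_hat,n_communities,
#' n_communities_min5`; interval endpoints are written with 12 significant
#' digits (an unbounded upper end as `inf`).
#'
#' @param env a `champ_envelope1d`.
#' @param path file path.
#' @export
write_domains_1d <- function(env, path) {
  d <- env$domains
  for (cl in c("n_communities", "n_communities_min5"))
    if (is.null(d[[cl]])) d[[cl]] <- NA
  lines <- c("partition_id,gamma_lo,gamma_hi,a_hat,p_hat,n_communities,n_communities_min5",
             apply(cbind(d$partition_id, fmt_num(d$gamma_lo),
                         fmt_num(d$gamma_hi), fmt_num(d$a_hat),
                         fmt_num(d$p_hat), d$n_communities,
                         d$n_communities_min5),
                   1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a 2-D domain map as JSON
#'
#' Per-domain objects carry `partition_id`, `vertices` (CCW, in
#' (gamma, omega) coordinates), `area` and the plane coefficients, plus a
#' top-level `out_of_box` id list and `adjacency` edge list with border
#' lengths.
#'
#' @param map a `champ_domains2d`.
#' @param path file path.
#' @export
write_domains_2d <- function(map, path) {
  doms <- lapply(map$domains, function(d) {
    rec <- d$record
    list(partition_id = d$partition_id,
         vertices = unname(apply(d$vertices, 1, as.numeric,
                                 simplify = FALSE)),
         area = d$area, a_hat = rec$a_hat, p_hat = rec$p_hat,
         c_hat = rec$c_hat,
         n_communities = if (!is.null(rec$n_communities))
           rec$n_communities else NA)
  })
  obj <- list(box = map$box, domains = doms,
              out_of_box = map$out_of_box,
              adjacency = map$adjacency,
              input_count = map$input_count,
              pruned_count = map$pruned_count)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_domains_2d
#' @return `read_domains_2d`: a `champ_domains2d` (without `co_optimal`).
#' @export
read_domains_2d <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  doms <- lapply(obj$domains, function(d) {
    v <- do.call(rbind, lapply(d$vertices, as.numeric))
    colnames(v) <- c("gamma", "omega")
    list(partition_id = d$partition_id, vertices = v, area = d$area,
         record = data.frame(partition_id = d$partition_id,
                             a_hat = d$a_hat, p_hat = d$p_hat,
                             c_hat = d$c_hat))
  })
  adj <- if (length(obj$adjacency)) {
    do.call(rbind, lapply(obj$adjacency, as.data.frame))
  } else {
    data.frame(id1 = integer(0), id2 = integer(0),
               border_length = numeric(0))
  }
  structure(list(domains = doms, adjacency = adj,
                 out_of_box = as.integer(unlist(obj$out_of_box)),
                 box = list(gamma = as.numeric(unlist(obj$box$gamma)),
                            omega = as.numeric(unlist(obj$box$omega))),
                 input_count = obj$input_count,
                 pruned_count = obj$pruned_count,
                 co_optimal = list()),
            class = "champ_domains2d")
}

#' Write a run manifest
#'
#' Records tool version, input file checksums, configuration values, the
#' master seed and a timestamp next to every CLI output, so a run can be
#' audited and reproduced.
#'
#' @param path manifest path.
#' @param inputs character vector of input file paths (checksummed).
#' @param config named list of configuration values.
#' @param seed master seed (or NA).
#' @export
write_manifest <- function(path, inputs, config, seed = NA) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(tool = "champr",
              version = as.character(utils::packageVersion("champr")),
              inputs = sums, config = config, seed = seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
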