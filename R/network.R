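#' Construct a signed logical signalling network
#'
#' A `logic_network` couples a node table (with roles) to a set of signed,
#' gated interactions, each carrying one named strength parameter. It is the
#' topology object every other function in the package consumes.
#'
#' Node roles follow the usual colour coding of logic-model diagrams:
#' `input` (experimentally clamped stimuli), `measured` (proteins with
#' quantitative readouts), `latent` (modelled but unmeasured) and `readout`
#' (functional endpoints such as apoptosis). A `constitutive` node is clamped
#' fully active unless overridden. Input and constitutive nodes may not have
#' incoming interactions.
#'
#' @param nodes data.frame with columns `name`, `role` (one of `"input"`,
#'   `"measured"`, `"latent"`, `"readout"`) and logical `constitutive`.
#' @param interactions data.frame with columns `id`, `target`, `gate`
#'   (`"single"`, `"AND"` or `"OR"`), `sign` (`"activation"` or
#'   `"inhibition"`), `parameter`, and a list column `sources` of character
#'   vectors.
#' @return An object of class `logic_network`.
#' @seealso [read_network()], [competition_groups()]
#' @export
logic_network <- function(nodes, interactions) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (is.null(nodes$constitutive)) nodes$constitutive <- FALSE
  nodes$constitutive <- as.logical(nodes$constitutive)
  net <- structure(list(nodes = nodes, interactions = interactions),
                   class = "logic_network")
  validate_network(net)
  net
}

node_roles <- c("input", "measured", "latent", "readout")

validate_network <- function(net) {
  nodes <- net$nodes
  ia <- net$interactions
  if (anyDuplicated(nodes$name))
    stop("schema error: duplicate node names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  bad_role <- setdiff(unique(nodes$role), node_roles)
  if (length(bad_role))
    stop("schema error: unknown node role(s): ", paste(bad_role, collapse = ", "))
  if (nrow(ia)) {
    all_src <- unlist(ia$sources)
    missing <- setdiff(c(all_src, ia$target), nodes$name)
    if (length(missing))
      stop("schema error: interaction references undeclared node(s): ",
           paste(unique(missing), collapse = ", "))
    if (anyDuplicated(ia$parameter))
      stop("schema error: duplicate parameter name(s): ",
           paste(unique(ia$parameter[duplicated(ia$parameter)]), collapse = ", "))
    nsrc <- vapply(ia$sources, length, integer(1))
    if (any((ia$gate == "single") != (nsrc == 1L)))
      stop("schema error: gate 'single' if and only if exactly one source")
    clamped <- nodes$name[nodes$role == "input" | nodes$constitutive]
    bad_tgt <- intersect(ia$target, clamped)
    if (length(bad_tgt))
      stop("schema error: interaction into input/constitutive node(s): ",
           paste(bad_tgt, collapse = ", "))
  }
  invisible(net)
}

#' Read a logical network from an interaction-list file
#'
#' The file dialect is a whitespace-delimited, SIF-like format, UTF-8, with
#' `#` comments. Node roles are declared in a header block of `@node`
#' directives; undeclared nodes default to role `latent`.
#'
#' ```
#' @node TRAIL input
#' @node AKT measured
#' @node BRAF latent constitutive
#' A  ->  B   k1          # activation
#' A  -|  B   k2          # inhibition
#' A&C -> B   k3          # AND gate (both sources required)
#' A+C -> B   k4          # OR gate (probabilistic union of sources)
#' ```
#'
#' @param file path to the network file, or a character vector of lines.
#' @return A validated [logic_network()].
#' @export
read_network <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  nodes <- data.frame(name = character(), role = character(),
                      constitutive = logical(), stringsAsFactors = FALSE)
  ia <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln]])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    if (tok[1] == "@node") {
      if (length(tok) < 2L)
        stop(sprintf("parse error at line %d: @node needs a name", ln))
      role <- if (length(tok) >= 3L && tok[3] != "constitutive") tok[3] else "latent"
      if (!role %in% node_roles)
        stop(sprintf("parse error at line %d: unknown role '%s'", ln, role))
      const <- "constitutive" %in% tok[-(1:2)]
      nodes <- rbind(nodes, data.frame(name = tok[2], role = role,
                                       constitutive = const,
                                       stringsAsFactors = FALSE))
      next
    }
    arrow_i <- which(tok %in% c("->", "-|"))
    if (length(arrow_i) != 1L || arrow_i != 2L || length(tok) < 4L)
      stop(sprintf("parse error at line %d: expected 'SRC -> TGT param' or 'SRC -| TGT param', got '%s'",
                   ln, raw))
    lhs <- tok[1]
    sign <- if (tok[2] == "->") "activation" else "inhibition"
    target <- tok[3]
    param <- tok[4]
    has_and <- grepl("&", lhs, fixed = TRUE)
    has_or <- grepl("+", lhs, fixed = TRUE)
    if (has_and && has_or)
      stop(sprintf("parse error at line %d: cannot mix '&' and '+' in one interaction", ln))
    sources <- strsplit(lhs, "[&+]")[[1]]
    gate <- if (has_and) "AND" else if (has_or) "OR" else "single"
    if (length(tok) >= 5L) {
      if (!tok[5] %in% c("AND", "OR", "single"))
        stop(sprintf("parse error at line %d: unknown gate '%s'", ln, tok[5]))
      if (tok[5] != gate)
        stop(sprintf("parse error at line %d: declared gate '%s' disagrees with source list", ln, tok[5]))
    }
    ia[[length(ia) + 1L]] <- list(target = target, gate = gate, sign = sign,
                                  parameter = param, sources = sources)
  }
  if (!length(ia)) stop("parse error: no interactions found")
  interactions <- data.frame(
    id = sprintf("r%d", seq_along(ia)),
    target = vapply(ia, `[[`, "", "target"),
    gate = vapply(ia, `[[`, "", "gate"),
    sign = vapply(ia, `[[`, "", "sign"),
    parameter = vapply(ia, `[[`, "", "parameter"),
    stringsAsFactors = FALSE)
  interactions$sources <- lapply(ia, `[[`, "sources")
  mentioned <- unique(c(unlist(interactions$sources), interactions$target))
  undeclared <- setdiff(mentioned, nodes$name)
  if (length(undeclared))
    nodes <- rbind(nodes, data.frame(name = undeclared, role = "latent",
                                     constitutive = FALSE, stringsAsFactors = FALSE))
  logic_network(nodes, interactions)
}

#' Write a logical network to its interaction-list format
#'
#' Inverse of [read_network()]: the produced file parses back to a network
#' with the same node set and the same interaction multiset.
#'
#' @param net a [logic_network()].
#' @param file path, or `""` to return the lines invisibly.
#' @return The file lines, invisibly.
#' @export
write_network <- function(net, file = "") {
  stopifnot(inherits(net, "logic_network"))
  hdr <- sprintf("@node %s %s%s", net$nodes$name, net$nodes$role,
                 ifelse(net$nodes$constitutive, " constitutive", ""))
  joiner <- ifelse(net$interactions$gate == "OR", "+", "&")
  lhs <- mapply(function(s, j) paste(s, collapse = j),
                net$interactions$sources, joiner)
  arrow <- ifelse(net$interactions$sign == "activation", "->", "-|")
  body <- sprintf("%s %s %s %s", lhs, arrow, net$interactions$target,
                  net$interactions$parameter)
  lines <- c(hdr, body)
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}

#' Activator competition groups of a network
#'
#' In the probabilistic logic model the strengths of the activating
#' interactions converging on one node compete: their parameters must sum to
#' exactly 1 within each context. Nodes with two or more incoming activation
#' interactions therefore contribute one competition group each. A node with
#' a single activator contributes no group — its weight is free in \[0,1\]
#' (applying the sum-to-one rule there would pin every chain weight at 1 and
#' make it non-identifiable). Inhibitory interactions always carry free,
#' independent weights.
#'
#' @param net a [logic_network()].
#' @return A list of character vectors of parameter names (possibly empty).
#' @export
competition_groups <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  ia <- net$interactions
  act <- ia[ia$sign == "activation", , drop = FALSE]
  out <- list()
  for (tgt in unique(act$target)) {
    p <- act$parameter[act$target == tgt]
    if (length(p) >= 2L) out[[length(out) + 1L]] <- sort(p)
  }
  out[order(vapply(out, `[[`, "", 1L))]
}

#' @export
print.logic_network <- function(x, ...) {
  nn <- nrow(x$nodes)
  ni <- nrow(x$interactions)
  cat(sprintf("Logical network: %d nodes, %d interactions (%d parameters)\n",
              nn, ni, length(unique(x$interactions$parameter))))
  tab <- table(factor(x$nodes$role, levels = node_roles))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("; constitutive=%d\n", sum(x$nodes$constitutive)))
  cg <- competition_groups(x)
  cat(sprintf("  competition groups: %d (%d constrained parameters)\n",
              length(cg), length(unlist(cg))))
  invisible(x)
}

#' Export a parsed network as JSON (provenance record)
#'
#' @param net a [logic_network()].
#' @param file optional path; if omitted the JSON string is returned.
#' @return JSON string, invisibly if written to a file.
#' @export
network_to_json <- function(net, file = NULL) {
  stopifnot(inherits(net, "logic_network"))
  obj <- list(nodes = net$nodes,
              interactions = net$interactions[c("id", "target", "gate", "sign", "parameter")],
              sources = stats::setNames(net$interactions$sources, net$interactions$id),
              competition_groups = competition_groups(net))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

# internal: node names clamped by default (inputs get explicit clamps,
# constitutive nodes default to 1)
clamped_names <- function(net) net$nodes$name[net$nodes$role == "input" | net$nodes$constitutive]
input_names <- function(net) net$nodes$name[net$nodes$role == "input"]
measured_names <- function(net) net$nodes$name[net$nodes$role == "measured"]
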