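#' @keywords internal
make_species <- function(name, role = c("enzyme-form", "free-ligand", "product"),
                         carries_substrate = FALSE, carries_inhibitor = FALSE) {
  role <- match.arg(role)
  if (role == "product" && (carries_substrate || carries_inhibitor))
    stop("a product species carries neither ligand flag", call. = FALSE)
  data.frame(name = name, role = role,
             carries_substrate = carries_substrate,
             carries_inhibitor = carries_inhibitor,
             stringsAsFactors = FALSE)
}

#' Elementary mass-action reaction
#'
#' A (possibly reversible) reaction with at most two reactant and two
#' product molecules and exactly one enzyme form on each side.  Rate
#' constants are 1/s for unimolecular and 1/(M s) for bimolecular steps;
#' `k_backward = 0` marks an irreversible step.
#'
#' @param reactants named numeric vector of stoichiometries, e.g.
#'   `c(E = 1, S = 1)`.
#' @param products named numeric vector of stoichiometries.
#' @param k_forward forward rate constant, > 0.
#' @param k_backward backward rate constant, >= 0.
#' @param label optional human-readable label.
#' @return A list of class `ma_reaction`.
#' @export
reaction <- function(reactants, products, k_forward, k_backward = 0,
                     label = NULL) {
  if (is.null(names(reactants)) || is.null(names(products)))
    stop("reactant and product stoichiometries must be named", call. = FALSE)
  if (sum(reactants) > 2 || sum(products) > 2)
    stop("total molecularity on each side must be <= 2", call. = FALSE)
  if (!is.numeric(k_forward) || k_forward <= 0)
    stop("k_forward must be > 0", call. = FALSE)
  if (!is.numeric(k_backward) || k_backward < 0)
    stop("k_backward must be >= 0", call. = FALSE)
  if (is.null(label))
    label <- paste0(paste(names(reactants), collapse = "+"),
                    if (k_backward > 0) "<->" else "->",
                    paste(names(products), collapse = "+"))
  structure(list(reactants = reactants, products = products,
                 k_forward = k_forward, k_backward = k_backward,
                 label = label),
            class = "ma_reaction")
}

#' Mass-action reaction network
#'
#' The executable form of a reaction-scheme diagram: a species table, a
#' list of elementary reactions and initial concentrations.  Networks are
#' normally built by [build_scheme()]; this constructor validates the
#' structural invariants (unique species names, every referenced species
#' declared, exactly one enzyme form on each side of every reaction,
#' positive total enzyme, nonnegative concentrations).
#'
#' @param species data frame with columns `name`, `role` (one of
#'   "enzyme-form", "free-ligand", "product"), `carries_substrate`,
#'   `carries_inhibitor`; build rows with the internal species helper or
#'   supply directly.
#' @param reactions list of [reaction()] objects.
#' @param init named numeric vector of initial concentrations, M.
#'   Missing species start at 0.
#' @param meta optional list of provenance (scheme variant, parameters).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, init = numeric(), meta = list()) {
  stopifnot(is.data.frame(species), is.list(reactions))
  if (anyDuplicated(species$name))
    stop("species names must be unique", call. = FALSE)
  enz <- species$name[species$role == "enzyme-form"]
  for (r in reactions) {
    if (!inherits(r, "ma_reaction")) stop("reactions must be ma_reaction objects")
    refd <- c(names(r$reactants), names(r$products))
    missing <- setdiff(refd, species$name)
    if (length(missing))
      stop("reaction '", r$label, "' references undeclared species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (sum(r$reactants[names(r$reactants) %in% enz]) != 1 ||
        sum(r$products[names(r$products) %in% enz]) != 1)
      stop("reaction '", r$label, "' must have exactly one enzyme form on each side",
           call. = FALSE)
  }
  if (length(init)) {
    unknown <- setdiff(names(init), species$name)
    if (length(unknown))
      stop("initial concentrations name unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(init < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  }
  full_init <- stats::setNames(numeric(nrow(species)), species$name)
  full_init[names(init)] <- init
  if (sum(full_init[enz]) <= 0)
    stop("total enzyme concentration must be > 0", call. = FALSE)
  structure(list(species = species, reactions = reactions,
                 init = full_init, meta = meta),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Mass-action reaction network: %d species, %d reactions\n",
              nrow(x$species), length(x$reactions)))
  if (!is.null(x$meta$variant))
    cat("  scheme variant:", x$meta$variant, "\n")
  cat("  species:", paste(x$species$name, collapse = ", "), "\n")
  for (r in x$reactions)
    cat(sprintf("  %-14s kf = %.4g  kb = %.4g\n", r$label,
                r$k_forward, r$k_backward))
  invisible(x)
}

#' Mass-action time derivatives
#'
#' Evaluates the right-hand side of the mass-action ODE system at a given
#' state vector.  Exact conservation is built in: every conservation law
#' of the network is annihilated by the returned derivative in exact
#' arithmetic.
#'
#' @param network a [reaction_network()].
#' @param state numeric vector of concentrations (M) in species order, or
#'   named in any order.
#' @param neg_tol concentrations more negative than `-neg_tol` signal an
#'   invalid state (default 1e-12 M, the solver noise floor).
#' @return Named numeric vector of derivatives, M/s.
#' @export
ode_rhs <- function(network, state, neg_tol = 1e-12) {
  sp <- network$species$name
  if (length(state) != length(sp))
    stop("state length (", length(state), ") does not match species count (",
         length(sp), ")", call. = FALSE)
  if (is.null(names(state))) names(state) <- sp else state <- state[sp]
  if (any(state < -neg_tol))
    stop("invalid state: negative concentration beyond tolerance", call. = FALSE)
  dx <- stats::setNames(numeric(length(sp)), sp)
  for (r in network$reactions) {
    vf <- r$k_forward * prod(state[names(r$reactants)] ^ r$reactants)
    vb <- if (r$k_backward > 0)
      r$k_backward * prod(state[names(r$products)] ^ r$products) else 0
    net <- vf - vb
    dx[names(r$reactants)] <- dx[names(r$reactants)] - net * r$reactants
    dx[names(r$products)]  <- dx[names(r$products)]  + net * r$products
  }
  dx
}

#' Conservation laws of a network
#'
#' Returns the linear combinations of species conserved by the dynamics:
#' total enzyme (sum of all enzyme forms), total substrate (free substrate
#' plus substrate-carrying enzyme forms plus product) and, when an
#' inhibitor is present, total inhibitor (free plus bound).
#'
#' @param network a [reaction_network()].
#' @return Named list of coefficient vectors over the species.
#' @export
conservation_laws <- function(network) {
  sp <- network$species
  zero <- stats::setNames(numeric(nrow(sp)), sp$name)
  laws <- list()
  enzyme <- zero; enzyme[sp$role == "enzyme-form"] <- 1
  laws$enzyme <- enzyme
  substrate <- zero
  substrate[sp$carries_substrate | sp$role == "product"] <- 1
  if (any(substrate > 0)) laws$substrate <- substrate
  inhibitor <- zero; inhibitor[sp$carries_inhibitor] <- 1
  if (any(inhibitor > 0)) laws$inhibitor <- inhibitor
  laws
}

#' Thermodynamic-cycle consistency report
#'
#' Finds an independent cycle basis of the undirected enzyme-state graph
#' (reversible reactions only; irreversible catalytic steps are excluded)
#' and reports, for each basis cycle, the product of forward/backward
#' rate-constant ratios taken around the cycle.  A thermodynamically
#' consistent network has affinity 1 on every cycle (free-ligand
#' concentrations cancel because any closed cycle binds and releases each
#' ligand equally often).
#'
#' @param network a [reaction_network()].
#' @param tol relative tolerance for flagging a cycle as inconsistent.
#' @return A data frame with columns `cycle` (vertex path), `affinity`
#'   and `consistent`; zero rows for an acyclic graph.
#' @export
detailed_balance_report <- function(network, tol = 1e-9) {
  enz <- network$species$name[network$species$role == "enzyme-form"]
  rev_idx <- which(vapply(network$reactions, function(r) r$k_backward > 0, logical(1)))
  empty <- data.frame(cycle = character(), affinity = numeric(),
                      consistent = logical(), stringsAsFactors = FALSE)
  if (!length(rev_idx)) return(empty)
  ends <- lapply(rev_idx, function(i) {
    r <- network$reactions[[i]]
    c(from = intersect(names(r$reactants), enz),
      to   = intersect(names(r$products), enz))
  })
  ed <- data.frame(from = vapply(ends, `[[`, "", "from"),
                   to = vapply(ends, `[[`, "", "to"),
                   rid = rev_idx, stringsAsFactors = FALSE)
  verts <- unique(c(ed$from, ed$to))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = verts))
  tree <- igraph::mst(g)  # unweighted: deterministic spanning tree
  tree_rids <- igraph::edge_attr(tree, "rid")
  chords <- ed[!(ed$rid %in% tree_rids), , drop = FALSE]
  if (!nrow(chords)) return(empty)
  res <- lapply(seq_len(nrow(chords)), function(j) {
    chord <- chords[j, ]
    sp <- igraph::shortest_paths(tree, from = chord$to, to = chord$from,
                                 output = "both")
    vpath <- names(sp$vpath[[1]])
    epath_rids <- igraph::edge_attr(tree, "rid", sp$epath[[1]])
    # traverse chord from -> to, then tree path to -> ... -> from
    aff <- edge_ratio(network, chord$rid, chord$from)
    cur <- vpath[1]
    for (k in seq_along(epath_rids)) {
      aff <- aff * edge_ratio(network, epath_rids[k], cur)
      cur <- vpath[k + 1]
    }
    data.frame(cycle = paste(c(chord$from, vpath), collapse = "-"),
               affinity = aff,
               consistent = abs(aff - 1) <= tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# ratio of rate constants for traversing reversible reaction `rid`
# starting from enzyme form `from`
#' @keywords internal
edge_ratio <- function(network, rid, from) {
  r <- network$reactions[[rid]]
  enz_r <- names(r$reactants)[names(r$reactants) %in%
                                network$species$name[network$species$role == "enzyme-form"]]
  if (identical(enz_r, from)) r$k_forward / r$k_backward
  else r$k_backward / r$k_forward
}

#' Serialize a network to JSON
#'
#' The document has three fields: `species` (array of objects with
#' `name`, `role`, `carries_substrate`, `carries_inhibitor`), `reactions`
#' (array of objects with `reactants` and `products` stoichiometry maps,
#' `k_forward`, `k_backward`, `label`) and `init` (map of species name to
#' molar concentration).
#'
#' @param network a [reaction_network()].
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
network_to_json <- function(network, path = NULL) {
  doc <- list(
    species = network$species,
    reactions = lapply(network$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           k_forward = r$k_forward, k_backward = r$k_backward,
           label = r$label)),
    init = as.list(network$init)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a network from JSON
#'
#' @param x a file path or JSON string produced by [network_to_json()].
#' @return A [reaction_network()].
#' @export
network_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  species <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(name = s$name, role = s$role,
               carries_substrate = isTRUE(s$carries_substrate),
               carries_inhibitor = isTRUE(s$carries_inhibitor),
               stringsAsFactors = FALSE)))
  reactions <- lapply(doc$reactions, function(r)
    reaction(unlist(r$reactants), unlist(r$products),
             r$k_forward, r$k_backward, label = r$label))
  reaction_network(species, reactions, init = unlist(doc$init))
}
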