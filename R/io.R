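# Readers/writers. All tabular formats are tab-delimited UTF-8 with a header
# row and '.' decimal; the literal token "inf" (any case, optionally signed)
# is accepted wherever an unbounded value makes sense.

num_or_inf <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  out[grepl("^\\+?inf(inity)?$", tolower(x))] <- Inf
  out[grepl("^-inf(inity)?$", tolower(x))] <- -Inf
  out
}

fmt_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "inf", "-inf"),
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}

#' Write a metabolic network in the plain JSON dialect
#'
#' The dialect mirrors the package reader: a `metabolites` table (id, e, y,
#' exchange, excretable), a `reactions` table (id, stoich as metabolite ->
#' coefficient map, lb, ub, alpha), the crowding `budget` and the `biomass`
#' definition. Infinite bounds are serialized as the strings "inf"/"-inf".
#'
#' @param network a `metabolic_network` (unsplit form is customary).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path) {
  S <- as.matrix(network$stoich)
  rxns <- lapply(seq_along(network$reaction_ids), function(j) {
    nz <- which(S[, j] != 0)
    list(id = network$reaction_ids[j],
         stoich = as.list(setNames(S[nz, j], network$metabolite_ids[nz])),
         lb = fmt_num(network$lb[[j]]), ub = fmt_num(network$ub[[j]]),
         alpha = network$cost[[j]])
  })
  mets <- lapply(seq_along(network$metabolite_ids), function(i) {
    id <- network$metabolite_ids[i]
    list(id = id, e = network$maintenance[[i]], y = network$biomass_coeff[[i]],
         exchange = id %in% network$exchange_ids,
         excretable = if (id %in% network$exchange_ids)
           unname(network$excretable[id]) else FALSE)
  })
  bio <- network$biomass
  if (bio$kind == "affine") bio$weights <- as.list(bio$weights)
  obj <- list(format = "maxentcc-model-v1",
              budget = fmt_num(network$budget),
              biomass = bio, metabolites = mets, reactions = rxns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a metabolic network (JSON dialect or minimal SBML L3/FBC)
#'
#' @param path model file.
#' @param dialect "json_tsv" (the package's plain JSON dialect, see
#'   [write_model()]) or "sbml".
#' @return a `metabolic_network`. Malformed stoichiometry, unknown metabolite
#'   references and lb > ub produce errors naming the offending entry.
#' @export
read_model <- function(path, dialect = c("json_tsv", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("no such file: ", path)
  if (dialect == "sbml") return(read_sbml(path))
  obj <- jsonlite::read_json(path)
  mets <- obj$metabolites; rxns <- obj$reactions
  mid <- vapply(mets, function(m) m$id, character(1))
  rid <- vapply(rxns, function(r) r$id, character(1))
  S <- matrix(0, length(mid), length(rid), dimnames = list(mid, rid))
  for (r in rxns) {
    for (nm in names(r$stoich)) {
      if (!nm %in% mid)
        stop2("reaction ", r$id, " references unknown metabolite ", nm)
      co <- suppressWarnings(as.numeric(r$stoich[[nm]]))
      if (is.na(co)) stop2("malformed stoichiometry in reaction ", r$id)
      S[nm, r$id] <- co
    }
  }
  lb <- num_or_inf(vapply(rxns, function(r) as.character(r$lb), character(1)))
  ub <- num_or_inf(vapply(rxns, function(r) as.character(r$ub), character(1)))
  if (any(lb > ub))
    stop2("lb > ub for reaction(s): ", paste(rid[lb > ub], collapse = ", "))
  bio <- obj$biomass
  if (identical(bio$kind, "affine"))
    bio$weights <- unlist(bio$weights)
  ex <- mid[vapply(mets, function(m) isTRUE(m$exchange), logical(1))]
  metabolic_network(
    metabolite_ids = mid, reaction_ids = rid, stoich = S, lb = lb, ub = ub,
    exchange_ids = ex,
    excretable = setNames(vapply(mets, function(m) isTRUE(m$excretable),
                                 logical(1)), mid)[ex],
    maintenance = setNames(vapply(mets, function(m) as.numeric(m$e %||% 0),
                                  numeric(1)), mid),
    biomass_coeff = setNames(vapply(mets, function(m) as.numeric(m$y %||% 0),
                                    numeric(1)), mid),
    cost = setNames(vapply(rxns, function(r) as.numeric(r$alpha %||% 0),
                           numeric(1)), rid),
    budget = num_or_inf(as.character(obj$budget %||% "inf")),
    biomass = bio)
}

# Minimal SBML Level 3 + FBC subset: species (boundaryCondition -> exchange),
# reactions with listOf(Reactants|Products), flux bounds through fbc
# attributes pointing at parameters. Enough for small curated models; not a
# libSBML replacement.
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mid <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(num_or_inf(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rid <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mid), length(rid), dimnames = list(mid, rid))
  lb <- numeric(length(rid)); ub <- numeric(length(rid))
  for (j in seq_along(rid)) {
    r <- rx[[j]]
    for (ref in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      m <- xml2::xml_attr(ref, "species")
      if (!m %in% mid) stop2("reaction ", rid[j], " references unknown species ", m)
      S[m, j] <- S[m, j] - as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% 1)
    }
    for (ref in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      m <- xml2::xml_attr(ref, "species")
      if (!m %in% mid) stop2("reaction ", rid[j], " references unknown species ", m)
      S[m, j] <- S[m, j] + as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% 1)
    }
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb[j] <- if (!is.na(lbid)) pval[[lbid]] else if (rev) -Inf else 0
    ub[j] <- if (!is.na(ubid)) pval[[ubid]] else Inf
  }
  keep <- !boundary
  ex_guess <- mid[boundary]
  # boundary species become exchanges: drop their balance rows, expose uptakes
  net_mid <- mid
  bio_rxn <- grep("biomass", rid, ignore.case = TRUE, value = TRUE)
  if (!length(bio_rxn))
    stop2("SBML model lacks a reaction with 'biomass' in its id; ",
          "set the biomass definition manually via the JSON dialect")
  metabolic_network(
    metabolite_ids = net_mid, reaction_ids = rid, stoich = S, lb = lb, ub = ub,
    exchange_ids = ex_guess,
    excretable = setNames(rep(TRUE, length(ex_guess)), ex_guess),
    biomass = list(kind = "reaction", reaction = bio_rxn[1]))
}

#' Read a medium table
#'
#' TSV columns `metabolite_id`, `c_mM`, `V_max` (token "inf" allowed), plus an
#' optional logical column `amino_acid`. With `amino_acid_rule = TRUE`,
#' amino-acid rows with an empty `V_max` receive V_i = V_g/10 (amino-acid
#' uptake is typically tenfold slower than sugar uptake).
#'
#' @param path TSV file.
#' @param amino_acid_rule apply the V_i = V_g/10 default.
#' @param V_g reference sugar uptake (mmol/gDW/h) for the rule.
#' @return a [medium()].
#' @export
read_medium <- function(path, amino_acid_rule = FALSE, V_g = 0.5) {
  tb <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("metabolite_id", "c_mM", "V_max")
  if (!all(need %in% names(tb)))
    stop2("medium table must have columns ", paste(need, collapse = ", "))
  cc <- num_or_inf(tb$c_mM)
  V <- num_or_inf(tb$V_max)
  if (any(cc < 0, na.rm = TRUE)) stop2("negative feed concentration in medium")
  if (amino_acid_rule && "amino_acid" %in% names(tb)) {
    aa <- tolower(trimws(tb$amino_acid)) %in% c("true", "1", "yes")
    V[aa & (is.na(V) | tb$V_max == "")] <- V_g / 10
  }
  if (any(is.na(cc)) || any(is.na(V)))
    stop2("unparseable numbers in medium rows: ",
          paste(tb$metabolite_id[is.na(cc) | is.na(V)], collapse = ", "))
  medium(tb$metabolite_id, cc, V)
}

#' Read a toxicity table
#'
#' TSV columns `metabolite_id`, `K_inhib_mM`, `tau_per_h_per_mM`; either value
#' may be empty for a given metabolite.
#'
#' @param path TSV file.
#' @return a [toxicity_model()].
#' @export
read_toxicity <- function(path) {
  tb <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("metabolite_id", "K_inhib_mM", "tau_per_h_per_mM")
  if (!all(need %in% names(tb)))
    stop2("toxicity table must have columns ", paste(need, collapse = ", "))
  K <- suppressWarnings(as.numeric(tb$K_inhib_mM))
  tau <- suppressWarnings(as.numeric(tb$tau_per_h_per_mM))
  toxicity_model(
    K_inhib = if (any(!is.na(K))) setNames(K[!is.na(K)],
                                           tb$metabolite_id[!is.na(K)]),
    tau = if (any(!is.na(tau))) setNames(tau[!is.na(tau)],
                                         tb$metabolite_id[!is.na(tau)]))
}

#' Read an enzymatic cost table and attach it to a network
#'
#' TSV columns `reaction_id`, `alpha_mg_h_per_mmol` (the cost alpha = MW/a,
#' molecular weight over specific activity, precomputed). Reactions absent
#' from the table are imputed with the median of the available costs — the
#' standard fallback when enzyme annotations are incomplete.
#'
#' @param network a `metabolic_network`.
#' @param path TSV file.
#' @param budget optional crowding budget C to set alongside (mg/mgDW;
#'   mammalian default 0.078).
#' @return the network with `cost` (and optionally `budget`) replaced;
#'   attribute `imputed` lists the reactions that received the median.
#' @export
read_costs <- function(network, path, budget = NULL) {
  tb <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("reaction_id", "alpha_mg_h_per_mmol")
  if (!all(need %in% names(tb)))
    stop2("cost table must have columns ", paste(need, collapse = ", "))
  alpha <- suppressWarnings(as.numeric(tb$alpha_mg_h_per_mmol))
  known <- tb$reaction_id[!is.na(alpha)]
  unknown_rows <- setdiff(known, network$reaction_ids)
  if (length(unknown_rows))
    stop2("cost table names unknown reaction(s): ",
          paste(unknown_rows, collapse = ", "))
  med <- stats::median(alpha[!is.na(alpha)])
  cost <- setNames(rep(med, length(network$reaction_ids)),
                   network$reaction_ids)
  cost[known] <- alpha[!is.na(alpha)]
  if (any(cost < 0)) stop2("negative cost coefficients")
  network$cost <- cost
  if (!is.null(budget)) network$budget <- budget
  attr(network, "imputed") <- setdiff(network$reaction_ids, known)
  network
}

#' Read toy parameters from a key = value config file
#'
#' Recognized keys: V_g, R, e, y, tau, c_g; missing keys keep the defaults of
#' [toy_params()]. Lines starting with `#` are comments.
#'
#' @param path config file.
#' @return a [toy_params()].
#' @export
read_toy_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop2("malformed config line(s): ",
                      paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- num_or_inf(vapply(kv, `[`, character(1), 2))
  known <- c("V_g", "R", "e", "y", "tau", "c_g")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop2("unknown key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(setNames(vals, keys))
  do.call(toy_params, args)
}

#' Random bounded fixture polytope with a guaranteed interior point
#'
#' The interior point is drawn first and the bounds and equality offsets are
#' constructed around it, so the polytope is never empty and the point is
#' strictly interior. The growth functional is a random affine form.
#'
#' @param n_vars number of variables (>= n_eq).
#' @param n_eq number of equality rows (>= 0).
#' @param seed integer seed (caller's RNG state preserved).
#' @return a [flux_polytope] with attribute `interior_point`.
#' @export
make_fixture_polytope <- function(n_vars, n_eq, seed = 1) {
  stopifnot(n_vars >= 1, n_eq >= 0, n_vars >= n_eq)
  with_seed(seed, function() {
    x0 <- runif(n_vars, 1, 2)
    l <- x0 - runif(n_vars, 0.3, 1.2)
    u <- x0 + runif(n_vars, 0.3, 1.2)
    E <- if (n_eq > 0) matrix(stats::rnorm(n_eq * n_vars), n_eq, n_vars) else
      matrix(0, 0, n_vars)
    d <- if (n_eq > 0) as.numeric(E %*% x0) else numeric(0)
    w <- stats::rnorm(n_vars)
    P <- flux_polytope(E, d, l, u, w, z0 = 0,
                       cost = runif(n_vars, 0.1, 1),
                       var_names = sprintf("x%02d", seq_len(n_vars)))
    attr(P, "interior_point") <- setNames(x0, P$var_names)
    P
  })
}

#' Write a sweep result as TSV
#'
#' @param sweep a `sweep_result` from [chemostat_sweep()] / [toy_sweep()].
#' @param path output file.
#' @param header_comment optional machine-readable run header written as
#'   `#`-prefixed lines (version, seed, options).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines(sprintf("# maxentcc %s",
                     as.character(utils::packageVersion("maxentcc"))), con)
  utils::write.table(as.data.frame(sweep), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
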