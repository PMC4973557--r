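#' Construct a stoichiometric network
#'
#' A light-weight container for constraint-based models: a metabolites table,
#' a reactions table with default flux bounds and roles, and the
#' stoichiometric matrix `S` (metabolites x reactions). Metabolites flagged
#' `balanced = FALSE` are storage pools (chlorophyll, beta-carotene) whose
#' rows are bookkeeping only: the steady-state constraint `S v = 0` applies
#' to balanced rows.
#'
#' Recognized roles: `biomass`, `photon` (photon exchange), `nitrate_met`
#' (metabolization of the internal nitrate store), `chl_acc`, `car_acc`
#' (accumulation fluxes), `ngam` (non-growth ATP maintenance), `exchange`
#' (any other exchange). Each of the first six must resolve to exactly one
#' reaction.
#'
#' Sign convention: for exchange and accumulation fluxes a negative value is
#' consumption/uptake, a positive value secretion/accumulation.
#'
#' @param metabolites tibble with columns `id`, `name`, `balanced`.
#' @param reactions tibble with columns `id`, `name`, `lb`, `ub`, `role`
#'   (`NA` for plain internal reactions).
#' @param S numeric matrix, metabolites x reactions, dimnames matching ids.
#' @return a validated `stoich_network` object.
#' @export
stoich_network <- function(metabolites, reactions, S) {
  net <- structure(
    list(metabolites = as_tibble(metabolites),
         reactions = as_tibble(reactions),
         S = S),
    class = "stoich_network"
  )
  validate_network(net)
}

required_roles <- c("biomass", "photon", "nitrate_met", "chl_acc", "car_acc", "ngam")

#' Validate a stoichiometric network
#'
#' Checks dimensions, role resolution (each required role exactly once),
#' absence of all-zero reaction columns, and bound ordering.
#'
#' @param network a `stoich_network`.
#' @return the network, invisibly usable in pipes; errors describe every
#'   violated invariant.
#' @export
validate_network <- function(network) {
  m <- network$metabolites; r <- network$reactions; S <- network$S
  problems <- character(0)
  if (nrow(S) != nrow(m) || ncol(S) != nrow(r)) {
    abort("S dimensions do not match metabolite/reaction tables")
  }
  if (!identical(rownames(S), m$id) || !identical(colnames(S), r$id)) {
    abort("S dimnames must equal metabolite and reaction ids")
  }
  zero_col <- colSums(S != 0) == 0
  if (any(zero_col)) {
    problems <- c(problems, paste0("all-zero stoichiometry column(s): ",
                                   paste(r$id[zero_col], collapse = ", ")))
  }
  if (any(r$lb > r$ub)) {
    problems <- c(problems, paste0("lb > ub for: ",
                                   paste(r$id[r$lb > r$ub], collapse = ", ")))
  }
  for (role in required_roles) {
    k <- sum(r$role %in% role)
    if (k != 1L) {
      cand <- r$id[grepl(role, r$id, ignore.case = TRUE)]
      problems <- c(problems, paste0(
        "role '", role, "' resolves to ", k, " reactions",
        if (k == 0L && length(cand)) paste0(" (candidates: ",
                                            paste(cand, collapse = ", "), ")")))
    }
  }
  if (length(problems)) {
    abort(paste0("invalid network:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  network
}

#' Role map of a network
#'
#' @param network a `stoich_network`.
#' @return named character vector, role -> reaction id.
#' @export
network_roles <- function(network) {
  r <- network$reactions
  has <- !is.na(r$role) & r$role != "exchange"
  setNames(r$id[has], r$role[has])
}

#' @export
print.stoich_network <- function(x, ...) {
  cat("<stoich_network> ", nrow(x$metabolites), "metabolites x",
      nrow(x$reactions), "reactions;",
      sum(!x$metabolites$balanced), "storage pool(s)\n")
  roles <- network_roles(x)
  cat("roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' The built-in toy photoautotroph network
#'
#' An 8-metabolite, 9-reaction stand-in for a genome-scale reconstruction,
#' small enough that every LP over it can be solved by hand or by exhaustive
#' vertex enumeration. Photons fix carbon skeletons (`PSY`, 20 photons per
#' CH2O + ATP pair) or feed cyclic electron flow (`CEF`, 10 photons per ATP);
#' internal nitrate is assimilated into a nitrogen carrier (`ASM`); the
#' chlorophyll and carotene accumulation fluxes exchange precursors with
#' storage pools; ATP maintenance (`NGAM`) is a demand whose turnover is
#' unbounded above, serving as the energy-dissipation route for excess light.
#' Biomass (h^-1) requires 40 CH2O + 3.5 N-carrier + 30 ATP, i.e. a hand-set
#' photon-per-biomass requirement of 20 x (40 + 3.5) = 870 when maintenance
#' is inactive.
#'
#' The biomass column carries small chlorophyll (0.027 mmol, i.e. 24 mg/gDw)
#' and beta-carotene (0.0014 mmol, 0.75 mg/gDw) composition coefficients on
#' the storage rows, from which default initial pigment fractions are taken.
#'
#' @return a `stoich_network`.
#' @export
toy_network <- function() {
  mets <- tibble(
    id = c("ph", "no3", "atp", "ch2o", "ncar", "chl", "car", "bio"),
    name = c("photon", "internal nitrate", "ATP", "carbon skeleton",
             "nitrogen carrier", "chlorophyll store", "beta-carotene store",
             "biomass"),
    balanced = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  rxns <- tibble(
    id = c("EX_photon", "EX_no3", "PSY", "CEF", "ASM",
           "ACC_chl", "ACC_car", "NGAM", "BIO"),
    name = c("photon exchange", "nitrate metabolization",
             "photosynthesis (linear)", "cyclic electron flow",
             "nitrate assimilation", "chlorophyll accumulation",
             "beta-carotene accumulation", "ATP maintenance", "growth"),
    lb = c(-1000, -0.19, 0, 0, 0, 0, 0, 0.183, 0),
    ub = c(0, 0, Inf, Inf, Inf, Inf, Inf, Inf, Inf),
    role = c("photon", "nitrate_met", NA, NA, NA,
             "chl_acc", "car_acc", "ngam", "biomass")
  )
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  S["ph", "EX_photon"] <- -1
  S["no3", "EX_no3"] <- -1
  S[c("ph", "ch2o", "atp"), "PSY"] <- c(-20, 1, 1)
  S[c("ph", "atp"), "CEF"] <- c(-10, 1)
  S[c("no3", "ch2o", "atp", "ncar"), "ASM"] <- c(-1, -1, -1, 1)
  S[c("ncar", "ch2o", "atp", "chl"), "ACC_chl"] <- c(-1, -1, -1, 1)
  S[c("ch2o", "atp", "car"), "ACC_car"] <- c(-4, -2, 1)
  S["atp", "NGAM"] <- -1
  S[c("ch2o", "ncar", "atp", "chl", "car", "bio"), "BIO"] <-
    c(-40, -3.5, -30, -0.027, -0.0014, 1)
  stoich_network(mets, rxns, S)
}

#' Biomass pigment composition of a network
#'
#' Reads the chlorophyll/carotene coefficients of the biomass column on the
#' storage rows and converts them to mass fractions; used for default initial
#' pigment states.
#'
#' @param network a `stoich_network`.
#' @param params model parameters (for the molar masses).
#' @return named vector `c(w_chl, w_car)` in g per g dry weight.
#' @export
biomass_composition <- function(network, params) {
  bio <- network_roles(network)[["biomass"]]
  s <- network$S[, bio]
  chl <- -sum(s[!network$metabolites$balanced &
                  grepl("chl", network$metabolites$id)])
  car <- -sum(s[!network$metabolites$balanced &
                  grepl("car", network$metabolites$id)])
  c(w_chl = max(0, chl) * params$m_chl, w_car = max(0, car) * params$m_car)
}

# ---------------------------------------------------------------------------
# JSON / SBML input-output
# ---------------------------------------------------------------------------

#' Read a stoichiometric network
#'
#' @param source path to a file (or, for JSON, a literal JSON string).
#' @param format `"json"` (the package's documented schema) or `"sbml"`
#'   (SBML Level 3 with FBC-style bound attributes).
#' @param roles optional named character vector role -> reaction id,
#'   overriding/supplying roles that are not stored in the file (SBML files
#'   do not carry them).
#' @return a validated `stoich_network`; unresolved roles are reported by
#'   name with candidate reaction ids.
#' @export
read_network <- function(source, format = c("json", "sbml"), roles = NULL) {
  format <- match.arg(format)
  net <- switch(format,
                json = read_network_json(source),
                sbml = read_network_sbml(source))
  if (!is.null(roles)) {
    net$reactions$role <- NA_character_
    for (ro in names(roles)) {
      j <- match(roles[[ro]], net$reactions$id)
      if (is.na(j)) abort(paste0("role '", ro, "': no reaction '", roles[[ro]], "'"))
      net$reactions$role[j] <- ro
    }
  }
  validate_network(net)
}

read_network_json <- function(source) {
  doc <- tryCatch(jsonlite::fromJSON(source, simplifyVector = FALSE),
                  error = function(e) abort(paste0("malformed network JSON: ",
                                                   conditionMessage(e))))
  mets <- purrr::map_dfr(doc$metabolites, function(m)
    tibble(id = m$id, name = m$name %||% m$id,
           balanced = m$balanced %||% TRUE))
  rx <- doc$reactions
  rxns <- purrr::map_dfr(rx, function(r)
    tibble(id = r$id, name = r$name %||% r$id,
           lb = bound_from_json(r$lb, -Inf), ub = bound_from_json(r$ub, Inf),
           role = r$role %||% NA_character_))
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (r in rx) {
    for (met in names(r$stoichiometry)) {
      if (!met %in% mets$id) {
        abort(paste0("reaction '", r$id, "' references unknown metabolite '",
                     met, "'"))
      }
      S[met, r$id] <- r$stoichiometry[[met]]
    }
  }
  structure(list(metabolites = mets, reactions = rxns, S = S),
            class = "stoich_network")
}

bound_from_json <- function(x, default) {
  if (is.null(x)) return(default)
  if (identical(x, "-Inf")) return(-Inf)
  if (identical(x, "Inf")) return(Inf)
  as.numeric(x)
}

#' Write a network to the package's JSON schema
#'
#' Schema: `{"metabolites": [{"id", "name", "balanced"}], "reactions":
#' [{"id", "name", "stoichiometry": {met: coef}, "lb", "ub", "role"}]}`.
#' Infinite bounds are encoded as the strings `"Inf"`/`"-Inf"`.
#'
#' @param network a `stoich_network`.
#' @param path output file.
#' @export
write_network_json <- function(network, path) {
  enc_bound <- function(x) if (is.infinite(x)) ifelse(x > 0, "Inf", "-Inf") else x
  doc <- list(
    metabolites = purrr::pmap(network$metabolites, function(id, name, balanced)
      list(id = id, name = name, balanced = balanced)),
    reactions = purrr::pmap(network$reactions, function(id, name, lb, ub, role) {
      s <- network$S[, id]
      s <- s[s != 0]
      out <- list(id = id, name = name, stoichiometry = as.list(s),
                  lb = enc_bound(lb), ub = enc_bound(ub))
      if (!is.na(role)) out$role <- role
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a network as SBML Level 3
#'
#' Emits a minimal SBML L3v1 document: species (storage pools marked with
#' `boundaryCondition="true"`), reactions with stoichiometric
#' `speciesReference`s, and flux bounds as `phyco:lb`/`phyco:ub` attributes
#' in a package annotation namespace (roles are not serialized; supply them
#' on read).
#'
#' @inheritParams write_network_json
#' @export
write_network_sbml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:phyco" = "https://phycoflux/ns", level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "phycoflux_model")
  comp <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "c", constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    xml2::xml_add_child(
      los, "species", id = m$id, name = m$name, compartment = "c",
      boundaryCondition = tolower(as.character(!m$balanced)),
      hasOnlySubstanceUnits = "false", constant = "false")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions[i, ]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = r$id, name = r$name,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "phyco:lb" = as.character(r$lb), "phyco:ub" = as.character(r$ub))
    s <- network$S[, r$id]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (met in names(reac)) {
        xml2::xml_add_child(lre, "speciesReference", species = met,
                            stoichiometry = as.character(-reac[[met]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (met in names(prod)) {
        xml2::xml_add_child(lpr, "speciesReference", species = met,
                            stoichiometry = as.character(prod[[met]]),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("malformed SBML: ",
                                                   conditionMessage(e))))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  mets <- tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    balanced = !(xml2::xml_attr(sp, "boundaryCondition") %in% "true")
  )
  rx <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  get_bound <- function(node, attr, default) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else as.numeric(v)
  }
  rxns <- purrr::map_dfr(rx, function(node) {
    tibble(id = xml2::xml_attr(node, "id"),
           name = dplyr::coalesce(xml2::xml_attr(node, "name"),
                                  xml2::xml_attr(node, "id")),
           lb = get_bound(node, "lb", -Inf),
           ub = get_bound(node, "ub", Inf),
           role = NA_character_)
  })
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (node in rx) {
    id <- xml2::xml_attr(node, "id")
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      S[xml2::xml_attr(sr, "species"), id] <-
        S[xml2::xml_attr(sr, "species"), id] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      S[xml2::xml_attr(sr, "species"), id] <-
        S[xml2::xml_attr(sr, "species"), id] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
  }
  structure(list(metabolites = mets, reactions = rxns, S = S),
            class = "stoich_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
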