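# SBML input/output and report writing.
#
# Two dialects are read: Level 3 with the fbc extension (bounds as
# parameters, gene associations as fbc:geneProductAssociation, objective in
# fbc:listOfObjectives) and Level 2 with COBRA-style annotations
# (LOWER_BOUND / UPPER_BOUND / OBJECTIVE_COEFFICIENT kinetic-law parameters,
# GENE_ASSOCIATION notes). Only toy models are ever written, always as
# L3+fbc. Following common practice, the SBML-mandated M_/R_/G_ identifier
# prefixes are stripped on read so model ids match the bare names users type.

# namespace-agnostic helpers -------------------------------------------------

.ln_all <- function(node, name, direct = FALSE) {
  xml2::xml_find_all(node, paste0(if (direct) "./" else ".//",
                                  "*[local-name()='", name, "']"))
}
.ln_first <- function(node, name) {
  xml2::xml_find_first(node, paste0(".//*[local-name()='", name, "']"))
}
# attribute lookup ignoring any namespace prefix
.attr_any <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- grepl(paste0("(^|:)", name, "$"), names(a))
  if (any(hit)) unname(a[hit][1]) else NA_character_
}

.strip_prefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

# fbc geneProductAssociation subtree -> GPR tree
.fbc_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    args <- lapply(kids, .fbc_gpr, gp_label = gp_label)
    args <- args[!vapply(args, is.null, logical(1))]
    if (!length(args)) return(NULL)
    if (length(args) == 1L) return(args[[1L]])
    return(list(op = nm, args = args))
  }
  if (nm == "geneProductRef") {
    ref <- .attr_any(node, "geneProduct")
    if (is.na(ref)) return(NULL)
    lab <- gp_label[[ref]]
    return(if (is.null(lab)) .strip_prefix(ref, "G") else lab)
  }
  NULL
}

#' Read an SBML metabolic model
#'
#' Parses SBML Level 3 (fbc extension) or Level 2 (COBRA note/kinetic-law
#' conventions) into a [metabolic_model()]. Flux bounds default to
#' `[-1000, 1000]` for reversible and `[0, 1000]` for irreversible reactions
#' when the file states none. A model without any objective loads with all
#' objective coefficients zero and a warning. `M_`/`R_`/`G_` identifier
#' prefixes are stripped.
#'
#' @param path path to an SBML file.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e))
  })
  mnode <- .ln_first(doc, "model")
  if (inherits(mnode, "xml_missing")) {
    stop("SBML parse error in '", path, "': no <model> element")
  }
  model_id <- .attr_any(mnode, "id")
  if (is.na(model_id)) model_id <- basename(path)

  # global parameters (L3 flux bounds live here)
  pars <- .ln_all(mnode, "parameter")
  par_val <- stats::setNames(
    as.numeric(vapply(pars, .attr_any, "", name = "value")),
    vapply(pars, .attr_any, "", name = "id"))

  # species
  sp <- .ln_all(mnode, "species")
  if (length(sp) == 0L) stop("structural error: model has no species")
  sp_id_raw <- vapply(sp, .attr_any, "", name = "id")
  boundary_sp <- vapply(sp, function(s) {
    identical(.attr_any(s, "boundaryCondition"), "true")
  }, logical(1))
  sp_id <- .strip_prefix(sp_id_raw, "M")
  metabolites <- data.frame(
    id = sp_id,
    name = ifelse(is.na(vapply(sp, .attr_any, "", name = "name")),
                  sp_id, vapply(sp, .attr_any, "", name = "name")),
    compartment = vapply(sp, .attr_any, "", name = "compartment"),
    stringsAsFactors = FALSE)
  metabolites <- metabolites[!boundary_sp, , drop = FALSE]
  id_map <- stats::setNames(sp_id, sp_id_raw)  # raw species id -> model id
  boundary_ids <- sp_id_raw[boundary_sp]

  # fbc gene products: id -> label
  gps <- .ln_all(mnode, "geneProduct")
  gp_label <- list()
  for (g in gps) {
    gid <- .attr_any(g, "id")
    lab <- .attr_any(g, "label")
    gp_label[[gid]] <- if (is.na(lab)) .strip_prefix(gid, "G") else lab
  }

  # fbc objective coefficients
  obj_coef <- numeric()
  objs <- .ln_all(mnode, "listOfObjectives")
  if (length(objs)) {
    active <- .attr_any(objs[[1]], "activeObjective")
    onodes <- .ln_all(objs[[1]], "objective")
    use <- onodes
    if (!is.na(active) && length(onodes) > 1L) {
      ids <- vapply(onodes, .attr_any, "", name = "id")
      use <- onodes[ids == active]
      if (!length(use)) use <- onodes
    }
    for (fo in .ln_all(use[[1]], "fluxObjective")) {
      rid <- .strip_prefix(.attr_any(fo, "reaction"), "R")
      obj_coef[rid] <- as.numeric(.attr_any(fo, "coefficient"))
    }
  }

  rx <- .ln_all(mnode, "reaction")
  if (length(rx) == 0L) {
    stop("structural error: model '", model_id, "' has no reactions")
  }
  n <- length(rx)
  rid <- character(n); rname <- character(n)
  lb <- numeric(n); ub <- numeric(n); oc <- numeric(n)
  stoich <- vector("list", n)
  gpr <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rx[[i]]
    raw <- .attr_any(r, "id")
    rid[i] <- .strip_prefix(raw, "R")
    nm <- .attr_any(r, "name")
    rname[i] <- if (is.na(nm)) rid[i] else nm
    reversible <- !identical(.attr_any(r, "reversible"), "false")

    # bounds: L3 fbc parameter refs, else L2 kinetic law, else defaults
    lref <- .attr_any(r, "lowerFluxBound")
    uref <- .attr_any(r, "upperFluxBound")
    lb[i] <- if (!is.na(lref) && lref %in% names(par_val)) par_val[[lref]]
             else if (reversible) -1000 else 0
    ub[i] <- if (!is.na(uref) && uref %in% names(par_val)) par_val[[uref]]
             else 1000
    kl <- .ln_first(r, "kineticLaw")
    if (!inherits(kl, "xml_missing")) {
      for (p in .ln_all(kl, "parameter")) {
        pid <- .attr_any(p, "id")
        pv <- as.numeric(.attr_any(p, "value"))
        if (identical(pid, "LOWER_BOUND")) lb[i] <- pv
        if (identical(pid, "UPPER_BOUND")) ub[i] <- pv
        if (identical(pid, "OBJECTIVE_COEFFICIENT") && is.finite(pv) && pv != 0) {
          obj_coef[rid[i]] <- pv
        }
      }
    }

    st <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      box <- .ln_all(r, side, direct = TRUE)
      if (!length(box)) next
      for (sr in .ln_all(box[[1]], "speciesReference")) {
        spec <- .attr_any(sr, "species")
        if (spec %in% boundary_ids) next
        coef <- .attr_any(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        key <- id_map[[spec]]
        if (is.null(key) || is.na(key)) key <- .strip_prefix(spec, "M")
        st[key] <- (if (key %in% names(st)) st[[key]] else 0) + sgn * coef
      }
    }
    stoich[[i]] <- st[st != 0]

    # gene association: fbc subtree preferred, GENE_ASSOCIATION notes fallback
    gassoc <- .ln_first(r, "geneProductAssociation")
    if (!inherits(gassoc, "xml_missing")) {
      kids <- xml2::xml_children(gassoc)
      if (length(kids)) gpr[[i]] <- .fbc_gpr(kids[[1]], gp_label)
    } else {
      notes <- .ln_first(r, "notes")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION:\\s*([^\n<]*)", txt))[[1]]
        if (length(m) == 2L && nzchar(trimws(m[2]))) {
          gpr[[i]] <- parse_gpr(m[2])
        }
      }
    }
  }
  names(stoich) <- rid
  names(gpr) <- rid
  oc <- ifelse(rid %in% names(obj_coef), obj_coef[rid], 0)
  oc[is.na(oc)] <- 0
  if (all(oc == 0)) {
    warning("model '", model_id,
            "' declares no objective; all objective coefficients set to 0")
  }

  metabolic_model(
    id = model_id,
    metabolites = metabolites,
    reactions = data.frame(id = rid, name = rname, lower_bound = lb,
                           upper_bound = ub, objective_coefficient = oc,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich,
    gpr = gpr)
}

# SBML writing (toy fixtures only) -------------------------------------------

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
.num <- function(x) sprintf("%.17g", x)
.safe_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.gpr_xml <- function(gpr, indent) {
  pad <- strrep(" ", indent)
  if (is.character(gpr)) {
    return(paste0(pad, "<fbc:geneProductRef fbc:geneProduct=\"G_",
                  .safe_sid(gpr), "\"/>"))
  }
  inner <- vapply(gpr$args, .gpr_xml, "", indent = indent + 2L)
  paste0(pad, "<fbc:", gpr$op, ">\n",
         paste(inner, collapse = "\n"), "\n",
         pad, "</fbc:", gpr$op, ">")
}

#' Write a model as SBML Level 3 with fbc
#'
#' Serializes a (small) model with full bounds, stoichiometry, gene
#' associations and objective, such that [read_sbml()] reproduces it exactly.
#' Identifiers are written with the conventional `M_`/`R_`/`G_` prefixes.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
  add('  <model id="', .safe_sid(model$id), '" fbc:strict="true">')

  comps <- unique(model$metabolites$compartment)
  add('    <listOfCompartments>')
  for (cmp in comps) {
    add('      <compartment id="', .safe_sid(cmp), '" constant="true"/>')
  }
  add('    </listOfCompartments>')

  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    add('      <species id="M_', model$metabolites$id[i],
        '" name="', .xml_escape(model$metabolites$name[i]),
        '" compartment="', .safe_sid(model$metabolites$compartment[i]),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
        'constant="false"/>')
  }
  add('    </listOfSpecies>')

  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- stats::setNames(paste0("bnd_", seq_along(bounds)), .num(bounds))
  add('    <listOfParameters>')
  for (b in bounds) {
    add('      <parameter id="', bid[[.num(b)]], '" value="', .num(b),
        '" constant="true"/>')
  }
  add('    </listOfParameters>')

  add('    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    st <- model$stoichiometry[[rid]]
    add('      <reaction id="R_', rid,
        '" name="', .xml_escape(model$reactions$name[i]),
        '" reversible="',
        if (model$reactions$lower_bound[i] < 0) "true" else "false",
        '" fast="false" fbc:lowerFluxBound="',
        bid[[.num(model$reactions$lower_bound[i])]],
        '" fbc:upperFluxBound="',
        bid[[.num(model$reactions$upper_bound[i])]], '">')
    for (side in c(-1, 1)) {
      sel <- st[sign(st) == side]
      if (!length(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      add('        <', tag, '>')
      for (met in names(sel)) {
        add('          <speciesReference species="M_', met,
            '" stoichiometry="', .num(abs(sel[[met]])),
            '" constant="true"/>')
      }
      add('        </', tag, '>')
    }
    g <- model$gpr[[rid]]
    if (!is.null(g)) {
      add('        <fbc:geneProductAssociation>')
      add(.gpr_xml(g, 10L))
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')

  nz <- which(model$reactions$objective_coefficient != 0)
  if (length(nz)) {
    add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    add('        <fbc:listOfFluxObjectives>')
    for (i in nz) {
      add('          <fbc:fluxObjective fbc:reaction="R_',
          model$reactions$id[i], '" fbc:coefficient="',
          .num(model$reactions$objective_coefficient[i]), '"/>')
    }
    add('        </fbc:listOfFluxObjectives>')
    add('      </fbc:objective>')
    add('    </fbc:listOfObjectives>')
  }
  if (length(model$genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      add('      <fbc:geneProduct fbc:id="G_', .safe_sid(g),
          '" fbc:label="', .xml_escape(g), '"/>')
    }
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(unlist(L), path)
  invisible(path)
}

# metabolite id resolution ----------------------------------------------------

#' Resolve a user-supplied metabolite identifier
#'
#' Accepts both the bracket dialect (`"frdp[c]"`) and the suffix dialect
#' (`"frdp_c"`), with or without an `M_` prefix, and resolves it against the
#' model's metabolite table. Normalizing an already-resolved id returns it
#' unchanged.
#'
#' @param text user-supplied metabolite id.
#' @param model a `metabolic_model`.
#' @return The matching metabolite id as stored in the model.
#' @export
normalize_metabolite_id <- function(text, model) {
  stopifnot(is.character(text), length(text) == 1L)
  t0 <- .strip_prefix(trimws(text), "M")
  m <- regexec("^(.*)\\[([^][]+)\\]$", t0)
  hit <- regmatches(t0, m)[[1]]
  cand <- if (length(hit) == 3L) paste0(hit[2], "_", hit[3]) else t0
  ids <- model$metabolites$id
  stripped <- .strip_prefix(ids, "M")
  matches <- unique(ids[stripped == cand | ids == cand])
  if (length(matches) == 1L) return(matches)
  if (length(matches) > 1L) {
    stop("ambiguous metabolite id '", text, "': matches ",
         paste(matches, collapse = ", "))
  }
  d <- utils::adist(cand, stripped)
  close <- ids[order(d)][seq_len(min(5L, length(ids)))]
  stop("no metabolite matching '", text, "' in model '", model$id,
       "'; closest ids: ", paste(close, collapse = ", "))
}

# report writing ---------------------------------------------------------------

.report_rows <- function(result) {
  cand <- result$candidates
  data.frame(
    rank = cand$rank,
    reaction_id = cand$reaction_id,
    reaction_name = cand$reaction_name,
    genes = vapply(cand$genes, paste, "", collapse = ";"),
    formula = cand$formula,
    flux_wt = cand$flux_wt,
    flux_opt = cand$flux_opt,
    ratio = cand$ratio,
    yield = cand$yield_value,
    module = cand$module,
    stringsAsFactors = FALSE)
}

.report_tsv_lines <- function(result) {
  df <- .report_rows(result)
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0L) return(header)
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.infinite(x), "Inf", sprintf("%.10g", x))
    } else as.character(x)
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
  c(header, body)
}

#' Write a ranked candidate report
#'
#' TSV reports carry one row per candidate with columns rank, reaction_id,
#' reaction_name, genes (semicolon-joined), formula, flux_wt, flux_opt,
#' ratio, yield, module; an infinite Ratio is written as the literal `Inf`.
#' JSON reports mirror the same fields and add run metadata (target, demand
#' reaction, biomass reaction, theoretical maximum yield, options).
#'
#' @param result a `upa_result` from [run_upa()].
#' @param path output file; `""` prints to stdout.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "upa_result"))
  if (nrow(result$candidates) == 0L) {
    warning("empty candidate list: writing header-only report")
  }
  lines <- if (format == "tsv") {
    .report_tsv_lines(result)
  } else {
    obj <- list(
      metadata = list(
        target_metabolite = result$target_metabolite,
        demand_id = result$demand_id,
        biomass_id = result$biomass_id,
        theoretical_max_yield = result$theoretical_max_yield,
        options = unclass(result$options)),
      candidates = .report_rows(result))
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE))
  }
  if (identical(path, "")) {
    writeLines(lines)
  } else {
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) {
                     stop("cannot write report to '", path, "': ",
                          conditionMessage(e))
                   })
  }
  invisible(path)
}
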