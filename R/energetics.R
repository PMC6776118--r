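#' Reaction step
#'
#' One step of a pathway instance: substrate/product stoichiometry plus a
#' signed integer count of ATP equivalents produced (+) or consumed (-).
#'
#' @param step_id short id.
#' @param enzyme gene symbol of the catalyzing enzyme (e.g. `"assK"`).
#' @param substrates,products named numeric vectors, compound -> coefficient
#'   (> 0).
#' @param atp_delta signed ATP equivalents.
#' @param note free-text rationale for the ATP accounting.
#' @return list of class `reaction_step`.
#' @export
reaction_step <- function(step_id, enzyme, substrates, products, atp_delta = 0,
                          note = "") {
  substrates <- unlist(substrates); products <- unlist(products)
  stopifnot(all(substrates > 0), all(products > 0),
            !is.null(names(substrates)), !is.null(names(products)))
  structure(list(step_id = step_id, enzyme = enzyme,
                 substrates = substrates, products = products,
                 atp_delta = atp_delta, note = note),
            class = "reaction_step")
}

#' Reaction ledger
#'
#' An ordered, non-empty list of [reaction_step()] composing one pathway
#' instance, with an optional compound -> elemental-formula map used by
#' [balance_check()].
#'
#' @param steps list of [reaction_step()].
#' @param formulas named character vector, compound -> formula (e.g.
#'   `c(propane = "C3H8")`).
#' @return list of class `reaction_ledger`.
#' @export
reaction_ledger <- function(steps, formulas = character(0)) {
  if (!length(steps)) stop("ledger must be non-empty")
  stopifnot(all(vapply(steps, inherits, TRUE, "reaction_step")))
  structure(list(steps = steps, formulas = unlist(formulas)),
            class = "reaction_ledger")
}

#' Path to the packaged alkane-fermentation ledger
#' @return file path under the installed package.
#' @export
default_ledger_file <- function()
  system.file("extdata", "alkane_fermentation_ledger.yaml",
              package = "magchar", mustWork = TRUE)

#' Read a reaction ledger from YAML
#'
#' Format: a `steps` list (step_id, enzyme, atp_delta, substrates, products,
#' note) and an optional `compounds` map of elemental formulas.
#'
#' @param path YAML file; defaults to the packaged propane-fermentation
#'   ledger.
#' @return a [reaction_ledger()].
#' @export
read_reaction_ledger <- function(path = default_ledger_file()) {
  raw <- yaml::read_yaml(path)
  steps <- lapply(raw$steps, function(s)
    reaction_step(s$step_id, s$enzyme, s$substrates, s$products,
                  s$atp_delta %||% 0, s$note %||% ""))
  reaction_ledger(steps, unlist(raw$compounds))
}

#' Net ATP yield of a ledger
#'
#' Sum of the per-step signed ATP equivalents; invariant to step order.
#'
#' @param ledger a [reaction_ledger()].
#' @return signed number of ATP per pathway instance.
#' @export
net_atp <- function(ledger) {
  stopifnot(inherits(ledger, "reaction_ledger"))
  sum(vapply(ledger$steps, `[[`, 0, "atp_delta"))
}

#' Net reaction of a ledger with intermediates canceled
#'
#' @param ledger a [reaction_ledger()].
#' @return list with named numeric vectors `substrates` and `products`.
#' @export
net_reaction <- function(ledger) {
  bal <- numeric(0)
  add <- function(bal, v, sign) {
    for (cmp in names(v)) {
      cur <- if (cmp %in% names(bal)) bal[[cmp]] else 0
      bal[cmp] <- cur + sign * v[[cmp]]
    }
    bal
  }
  for (s in ledger$steps) {
    bal <- add(bal, s$substrates, -1)
    bal <- add(bal, s$products, +1)
  }
  bal <- bal[abs(bal) > 1e-9]
  list(substrates = -bal[bal < 0], products = bal[bal > 0])
}

#' Read a compound formation-energy table
#'
#' TSV with columns `compound`, `dgf_kj_mol` (standard Gibbs free energy of
#' formation), `phase` (`aqueous`/`gas`/`liquid`) and optional `formula`.
#' Lines starting with `#` are comments. The packaged table under
#' `inst/extdata/formation_energies.tsv` carries approximate literature
#' values with provenance comments and is meant to be replaced or extended
#' by the user.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data frame of class `energy_table`.
#' @export
read_energy_table <- function(path = system.file("extdata", "formation_energies.tsv",
                                                 package = "magchar", mustWork = TRUE)) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("compound", "dgf_kj_mol", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("energy table missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(is.finite(df$dgf_kj_mol)),
            all(df$phase %in% c("aqueous", "gas", "liquid")))
  class(df) <- c("energy_table", "data.frame")
  df
}

energy_lookup <- function(compounds, table) {
  if (inherits(table, "data.frame"))
    table <- setNames(table$dgf_kj_mol, table$compound)
  missing <- setdiff(compounds, names(table))
  if (length(missing))
    stop("compound(s) missing from energy table: ", paste(missing, collapse = ", "))
  table[compounds]
}

#' Standard Gibbs free energy of a reaction
#'
#' `dG0 = sum(coeff * dGf(products)) - sum(coeff * dGf(substrates))` with all
#' species at standard state (1 M solutes, 1 atm gases, 25 C). A compound
#' absent from the table raises an error naming it.
#'
#' @param reaction list with named numeric vectors `substrates` and
#'   `products` (a [reaction_step()] works), or a [reaction_ledger()] whose
#'   [net_reaction()] is used.
#' @param table an [read_energy_table()] data frame or a named numeric vector
#'   of formation energies (kJ/mol).
#' @return dG0 in kJ/mol.
#' @export
delta_g_standard <- function(reaction, table) {
  if (inherits(reaction, "reaction_ledger")) reaction <- net_reaction(reaction)
  sub <- reaction$substrates; prod <- reaction$products
  sum(prod * energy_lookup(names(prod), table)) -
    sum(sub * energy_lookup(names(sub), table))
}

# Parse "C7H12O4" into named element counts.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) stop("unparsable formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

#' Elemental balance check of a reaction or ledger
#'
#' Verifies conservation of C, H, O, N, S and P between substrates and
#' products, using the ledger's compound formulas (or a supplied map). An
#' empty reaction is vacuously balanced; a compound lacking a formula raises
#' an error.
#'
#' @param reaction a [reaction_step()], a `list(substrates=, products=)`, or
#'   a [reaction_ledger()] (every step is then checked).
#' @param formulas named character vector compound -> formula; taken from the
#'   ledger when omitted.
#' @param elements elements to check.
#' @return list: `ok` (logical) and `deficits` (named numeric vector of
#'   product-minus-substrate atom counts for unbalanced elements; per step id
#'   for ledgers).
#' @export
balance_check <- function(reaction, formulas = NULL,
                          elements = c("C", "H", "O", "N", "S", "P")) {
  if (inherits(reaction, "reaction_ledger")) {
    formulas <- formulas %||% reaction$formulas
    res <- lapply(reaction$steps, balance_check, formulas = formulas,
                  elements = elements)
    names(res) <- vapply(reaction$steps, `[[`, "", "step_id")
    bad <- res[!vapply(res, `[[`, TRUE, "ok")]
    return(list(ok = !length(bad),
                deficits = lapply(bad, `[[`, "deficits")))
  }
  side_counts <- function(v) {
    out <- setNames(numeric(length(elements)), elements)
    for (cmp in names(v)) {
      if (!cmp %in% names(formulas)) stop("compound lacking a formula: ", cmp)
      f <- formulas[[cmp]]
      cnt <- parse_formula(f)
      for (el in intersect(names(cnt), elements))
        out[el] <- out[el] + v[[cmp]] * cnt[[el]]
    }
    out
  }
  sub <- reaction$substrates %||% numeric(0)
  prod <- reaction$products %||% numeric(0)
  diff <- side_counts(prod) - side_counts(sub)
  bad <- diff[abs(diff) > 1e-9]
  list(ok = !length(bad), deficits = bad)
}

#' Energetics summary of a ledger
#'
#' @param ledger a [reaction_ledger()].
#' @param table optional energy table for per-step and net dG0 (steps whose
#'   compounds are absent get `NA`).
#' @return list: `net_atp`, `balanced`, `per_step` data frame, `dg_net`.
#' @export
summarize_energetics <- function(ledger, table = NULL) {
  per <- do.call(rbind, lapply(ledger$steps, function(s) {
    dg <- if (!is.null(table))
      tryCatch(delta_g_standard(s, table), error = function(e) NA_real_)
    else NA_real_
    data.frame(step_id = s$step_id, enzyme = s$enzyme, atp_delta = s$atp_delta,
               dg0_kj_mol = dg, stringsAsFactors = FALSE)
  }))
  dg_net <- if (!is.null(table))
    tryCatch(delta_g_standard(ledger, table), error = function(e) NA_real_)
  else NA_real_
  list(net_atp = net_atp(ledger),
       balanced = balance_check(ledger)$ok,
       per_step = per, dg_net = dg_net)
}
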