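# Shared helpers: fixtures are always built in code, never stored.

# multiply every flux bound by k (growth-condition rescaling)
scale_bounds <- function(model, k) {
  model$reactions$lower_bound <- model$reactions$lower_bound * k
  model$reactions$upper_bound <- model$reactions$upper_bound * k
  model
}

expect_flux <- function(state, id, value, tol = 1e-6) {
  expect_equal(unname(state$fluxes[[id]]), value, tolerance = tol)
}

# oracle-side lexicographic solve: maximize primary by enumeration, clamp it,
# maximize secondary by enumeration. Independent of lexicographic_opt().
oracle_lex <- function(model, primary_id, secondary_id, fixed = list()) {
  model <- apply_fixed(model, fixed)
  s1 <- oracle_solve(model, primary_id)
  if (s1$status != "optimal") return(list(primary = NA_real_, secondary = NA_real_))
  i <- match(primary_id, model$reactions$id)
  model$reactions$lower_bound[i] <- s1$objective_value
  model$reactions$upper_bound[i] <- s1$objective_value
  s2 <- oracle_solve(model, secondary_id)
  list(primary = s1$objective_value,
       secondary = if (s2$status == "optimal") s2$objective_value else NA_real_)
}

apply_fixed <- function(model, fixed) {
  for (rid in names(fixed)) {
    i <- match(rid, model$reactions$id)
    model$reactions$lower_bound[i] <- fixed[[rid]]
    model$reactions$upper_bound[i] <- fixed[[rid]]
  }
  model
}

# close the product demand, as the wild-type solve does
close_demand <- function(model, demand_id) {
  i <- match(demand_id, model$reactions$id)
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

# minimal SBML L2 document with COBRA-style notes, for dialect tests
l2_sbml_text <- function() {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="l2toy">',
    '    <listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="M_s_e" name="substrate" compartment="e"/>',
    '      <species id="M_a_c" name="A" compartment="c"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="R_EX_s" reversible="true">',
    '        <listOfReactants><speciesReference species="M_s_e"/></listOfReactants>',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
    '          <listOfParameters>',
    '            <parameter id="LOWER_BOUND" value="-10"/>',
    '            <parameter id="UPPER_BOUND" value="1000"/>',
    '            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>',
    '          </listOfParameters>',
    '        </kineticLaw>',
    '      </reaction>',
    '      <reaction id="R_T1" reversible="false">',
    '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '          <p>GENE_ASSOCIATION: (g1 and g2) or g3</p>',
    '        </body></notes>',
    '        <listOfReactants><speciesReference species="M_s_e"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="M_a_c"/></listOfProducts>',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
    '          <listOfParameters>',
    '            <parameter id="LOWER_BOUND" value="0"/>',
    '            <parameter id="UPPER_BOUND" value="1000"/>',
    '            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>',
    '          </listOfParameters>',
    '        </kineticLaw>',
    '      </reaction>',
    '      <reaction id="R_BIO" reversible="false">',
    '        <listOfReactants><speciesReference species="M_a_c"/></listOfReactants>',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
    '          <listOfParameters>',
    '            <parameter id="LOWER_BOUND" value="0"/>',
    '            <parameter id="UPPER_BOUND" value="1000"/>',
    '            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '          </listOfParameters>',
    '        </kineticLaw>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
}
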