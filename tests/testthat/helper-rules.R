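# Minimal single-rule violation cases shared by the validation and
# acceptance suites.
rule_cases <- list(
  R1_unknown_term = list(overrides = list(omp_term_id = "OMP:9999999"), rule = "R1"),
  R2_unknown_evidence = list(overrides = list(eco_id = "ECO:9999999"), rule = "R2"),
  R3_dependent_without_reference = list(
    overrides = list(omp_term_id = "OMP:0000041", relative_to = NULL,
                     extensions = list()), rule = "R3"),
  R4_dangling_reference = list(
    overrides = list(),
    tweak = function(repo, ann, ref) {
      ann$relative_to <- "OMP_AN:0009999"
      repo$annotations[[ann$annotation_id]] <- ann
      ann
    },
    rule = "R4"),
  R5_unknown_qualifier = list(overrides = list(qualifier = "Maybe"), rule = "R5"),
  R6_same_strain_same_genotype = list(
    overrides = list(qualifier = "Same phenotype as reference strain",
                     genotype_id = "OMP_ST:0000001"), rule = "R6"),
  R7_same_condition_other_genotype = list(
    overrides = list(qualifier = "Same phenotype as in reference condition"),
    rule = "R7"),
  R8_malformed_extension = list(
    overrides = list(extensions = list(omp_extension("not a curie",
                                                     "CHEBI:74728"))),
    rule = "R8"),
  R9_reference_not_a_curie = list(
    overrides = list(reference = "no curie here"), rule = "R9"),
  R10_disallowed_condition_key = list(
    overrides = list(conditions = omp_conditions(humidity = "80%")),
    rule = "R10")
)

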