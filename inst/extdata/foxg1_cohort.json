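{
  "fixture": "foxg1_cohort",
  "version": "1.0",
  "n_cases": 14,
  "description": "Published clinical, genetic and neuroimaging features of 14 individuals with FOXG1 syndrome carrying intragenic heterozygous FOXG1 variants (5 in-house cases, 9 literature cases).",
  "columns": {
    "case_id": "integer 1-14",
    "variant_id": "compact one-letter protein change label",
    "cdna_change": "HGVS c. string (NM_005249.5 numbering)",
    "protein_change": "HGVS p. string, three-letter",
    "coding_effect": "missense | nonsense | frameshift",
    "protein_position": "first altered amino-acid residue",
    "domain": "N_terminal | FBD_CS | FBD | C_terminal",
    "sex": "M | F",
    "age_months": "age at clinical assessment, months",
    "microcephaly": "yes | none | unknown",
    "clinical_severity": "mild | moderate | severe (band of css)",
    "css": "clinical severity score, mean of 17 items rated 0-2, printed at 2 dp",
    "age_at_mri_months": "age at MRI, months",
    "mri_severity": "normal | mild | moderate | severe (band of mri_ss)",
    "mri_ss": "brain-MRI severity score, sum of 5 items, 0-6",
    "source": "our_case or literature reference tag"
  },
  "provenance_notes": [
    "The source publication's Results text twice prints 'R203H' in variant lists where the cohort table and figure context identify the variant as R230H (c.689G>A). The two strings are treated as one variant, R230H; no case numbered around residue 203 exists in the cohort table.",
    "Domain assignments for truncating variants refer to the domain of the first altered residue."
  ]
}
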