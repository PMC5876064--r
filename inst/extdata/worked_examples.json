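[
  {
    "schema_version": "1.0",
    "variant": {
      "gene": "MYH7",
      "transcript": "NM_000257.3",
      "hgvs_c": "c.4258C>T",
      "hgvs_p": "p.Arg1420Trp",
      "consequence": "missense",
      "aa_position": 1420,
      "in_repeat_region": false
    },
    "disease_context": "HCM",
    "population_frequencies": [
      {
        "population": "NFE",
        "ac": 1,
        "an": 66740,
        "deeply_characterized": true
      }
    ],
    "probands": [
      {
        "id": "R1420W-P01",
        "cohort": "cohort-2",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P02",
        "cohort": "cohort-3",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P03",
        "cohort": "cohort-4",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P04",
        "cohort": "cohort-1",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P05",
        "cohort": "cohort-2",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P06",
        "cohort": "cohort-3",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P07",
        "cohort": "cohort-4",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P08",
        "cohort": "cohort-1",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P09",
        "cohort": "cohort-2",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P10",
        "cohort": "cohort-3",
        "phenotype": "HCM",
        "duplicate_of": null
      },
      {
        "id": "R1420W-P11",
        "cohort": "cohort-4",
        "phenotype": "HCM",
        "duplicate_of": null
      }
    ],
    "segregations": [],
    "de_novo": [],
    "functional": [],
    "annotation": {
      "computational_consensus": "pathogenic-supporting",
      "same_aa_known_pathogenic": false,
      "other_change_at_pathogenic_residue": false,
      "in_trans_no_severity": false,
      "in_cis_with_pathogenic": false,
      "alternate_molecular_basis": false,
      "splice_no_impact_not_conserved": false
    },
    "expert_override": {
      "classification": "likely pathogenic",
      "justification": "additional probands not counted under the conservative counting approach"
    }
  },
  {
    "schema_version": "1.0",
    "variant": {
      "gene": "MYH7",
      "transcript": "NM_000257.3",
      "hgvs_c": "c.5726G>C",
      "hgvs_p": "p.Arg1909Pro",
      "consequence": "missense",
      "aa_position": 1909,
      "in_repeat_region": false
    },
    "disease_context": "DCM",
    "population_frequencies": [
      {
        "population": "NFE",
        "ac": 0,
        "an": 66740,
        "deeply_characterized": true
      }
    ],
    "probands": [],
    "segregations": [],
    "de_novo": [
      {
        "paternity_confirmed": false,
        "maternity_confirmed": true,
        "parents_genotype_negative": true,
        "parents_phenotype_negative": true,
        "family_history_negative": true
      }
    ],
    "functional": [],
    "annotation": {
      "computational_consensus": "pathogenic-supporting",
      "same_aa_known_pathogenic": false,
      "other_change_at_pathogenic_residue": false,
      "in_trans_no_severity": false,
      "in_cis_with_pathogenic": false,
      "alternate_molecular_basis": false,
      "splice_no_impact_not_conserved": false
    },
    "expert_override": {
      "classification": "likely pathogenic",
      "justification": "phenotype included DCM and myopathy; additional segregations observed"
    }
  }
]
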