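# Optional reference data (not redistributed)

The acceptance checks that compare against published reference values
look here for user-supplied files:

- `mycg_bound.pdb`   — deposited solution structure of substrate-bound MycG
- `rep2.pdb`         — representative substrate-free conformer (REP2),
                       solvent removed
- `cyp101a1_bound.pdb` — deposited solution structure of camphor-bound
                       CYP101A1
- `correspondence.tsv` — two-column residue pair list (CYP101A1 residue,
                       MycG residue) from a structure-based alignment
- `sequences.fasta`  — CYP101A1 and MycG amino-acid sequences

None of these files ship with the package; without them the
corresponding checks in tests/testthat/test-acceptance.R report failure
with an explanatory message. Everything else in the package is verified
on synthetic data with planted ground truth.
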