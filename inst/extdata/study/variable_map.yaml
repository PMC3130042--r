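# Role -> workspace-variable mapping for the deposited study MAT workspace.
# Place the (non-redistributable) workspace file beside this map as
# workspace.mat and edit the right-hand sides to match its variable names;
# see ?read_mat_workspace for the role contract.
intensities: intensities    # features x samples, log2 scale
protein_id: protein_id      # char array, one row per feature ("" = unidentified)
feature_id: feature_id      # optional
sample_id: sample_id        # optional
genotype: genotype          # C-allele counts 0/1/2 or genotype strings
sex: sex                    # "male"/"female" or 1 = male
race: race                  # strings or 1 = Caucasian
outcome: outcome            # "SVR"/"NR" or 1 = SVR (optional)
scores: scores              # optional precomputed metaprotein scores
score_names: score_names    # optional
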