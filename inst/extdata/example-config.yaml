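# Example run configuration for run_all(); see ?load_config for the schema.
n_neurons: 120
N_E_grid: [60, 72, 84, 96, 108]
lambda_grid: [0.1]
patch_side: 8
n_train_patches: 800
n_eval_patches: 30
n_boot: 60
stimuli: onef
n_images: 5
image_side: 96
spectral_exponent: 1
train: {n_iter: 50, infer_iter: 50, infer_tol: 1.0e-4}
lca: {max_steps: 1500, tol: 1.0e-5}
seed: 1
outdir: results/example
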