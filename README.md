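# erpauth

EEG identity authentication from event-related potentials (ERPs), built
around a multi-scale convolutional network family and a
spatial–temporal–frequency tensor representation.

## The problem

In the name-oddball paradigm a subject watches a randomized stream of
names — their own (rare), familiar names, strangers' names, and blank
screens — while 16-channel EEG is recorded. The subject's own name evokes
a characteristic ERP sequence (P200 ≈ 200 ms, a dominant P300 in
375–625 ms, and a late negativity), strongest over frontal/central
electrodes and concentrated below 10 Hz. Authentication is a per-subject
binary decision on a *single trial*: genuine (own name) versus impostor
(any other name).

`erpauth` is for researchers who want to study this pipeline end to end
without access to a recorded cohort: it ships a synthetic oddball-ERP
generator with controllable effect sizes, the full preprocessing chain,
the tensor representation, a declarative network builder, and the two
standard evaluation protocols.

## The model

Each trial is represented as a **16 × 94 × 60 tensor**
(channel × time × frequency): per channel, a short-time Fourier
spectrogram (Hamming window 64, hop 7, 256-point FFT, one-sided power) of
the 0–800 ms segment, resampled onto a canonical grid whose pixel measures
≈ 8.5 ms × 0.5 Hz.

Networks are stacks of 3–5 *multi-scale modules*. A module applies a 1 × 1
channel-mixing convolution, then `B` parallel branch convolutions with
kernels of different sizes `k_b` (3D kernels are
spatial × temporal × frequency with spatial size 6). Branch `b` is padded
by `(k_b − k_min)/2` per axis so all branches emit equal dimensions, then
batch-norm, leaky-ReLU (slope 0.01), channel concatenation and max
pooling. The head is dropout(0.4) → linear → leaky-ReLU → dropout(0.4) →
linear → softmax over {impostor, genuine}. Training is softmax
cross-entropy with Adam (default lr 5·10⁻⁴, 5 epochs, batch 50),
kaiming-uniform initialization, and population batch-norm statistics
frozen after training. Accuracy is estimated by stratified within-subject
5-fold cross-validation, or by repeated disjoint cohort splits with
per-subject models.

The convolution engine is implemented in the package (Rcpp/Armadillo,
im2col + GEMM with a masked-union-kernel schedule for multi-branch
modules); no external deep-learning framework is used.

## Worked example

Simulate one subject of a small cohort (strong oddball margin for the
demo), preprocess the continuous recording, tensorize, and estimate
authentication accuracy with the three-branch long-kernel 2D network at
desk-scale width:

```r
library(erpauth)

cohort <- cohort_spec(n_subjects = 2,
                      trials = c(self = 30, familiar = 15,
                                 stranger = 15, blank = 10),
                      noise_level = 5, margin = 1, seed = 42)
rec <- simulate_recording(cohort, 1)
rec
#> eeg_recording: 16 channels x 24719 samples @ 256 Hz, 70 markers

epochs  <- preprocess_recording(rec)            # filter, reref, epoch, reject
epochs  <- blank_baseline_subtract(epochs, blank_average(epochs))
tensors <- stack_tensor(epochs)
tensors
#> eeg_tensors: 60 trials x (16 x 94 x 60)
#>   calibration: 8.51 ms x 0.50 Hz per pixel

spec <- table1_specs(width = 1 / 6)[["2d_ms_length"]]
report <- evaluate_within_subject(spec, tensors, folds = 5,
  control = train_control(learning_rate = 5e-3, epochs = 10,
                          batch_size = 12), seed = 1)
report
#> eval_report [within_subject_cv]: accuracy 0.700 +/- 0.046 over 5 folds
round(report$accuracies, 3)
#> [1] 0.667 0.667 0.667 0.750 0.750
```

Mean accuracy 0.70 means 70% of held-out single trials were correctly
classified as genuine/impostor for this subject at these settings; chance
is 0.5 on this balanced set, and accuracy rises with the oddball margin,
trial count and training schedule.

Receptive-field calibration maps kernel pixels to physical units, and the
audit table recomputes every published extent, flagging cells whose
printed values disagree with pixel arithmetic:

```r
kernel_physical_extent(c(3, 3))
#>   ms   hz
#> 25.5  1.5
subset(calibration_table(), flagged)[, c("temporal", "frequency",
                                         "printed_hz", "computed_hz")]
#>    temporal frequency printed_hz computed_hz
#> 4         9         9        5.5         4.5
#> 12        3         7        5.5         3.5
#> 13        3         9        5.5         4.5
#> 15        5         9        5.5         4.5
#> 16        7         9        5.5         4.5
```

Other entry points: `kernel_sweep()` (16 single-kernel networks, ranked),
`strategy_compare()` (the ten shipped architectures), `branch_depth_grid()`
(2–6 branches × 3–5 modules), `feature_heatmap()` (z-scored branch
attention maps), `evaluate_cohort()` (repeated disjoint subject splits),
and `write_cohort()`/`read_recording()` for on-disk cohorts. A thin
command-line wrapper over the simulation/preprocessing/tensorization steps
is in `inst/scripts/erpauth-cli.R`. See the methods vignette
(`vignettes/erpauth-methods.Rmd`) for the model, its assumptions, the
desk-scale experiment regime, and known limitations.

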