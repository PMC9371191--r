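# histograde

Quantitative analysis of H&E-stained breast histopathology images along two
of the three structural axes of the Nottingham Grading System (NGS):
**tubule formation** and **nuclear pleomorphism**. The package segments cell
nuclei, measures their shape, scores candidate tubules, and classifies the
differentiation grade from nucleus features — and it ships a synthetic H&E
phantom generator with exact ground truth, so every stage is testable
without access to expert-labeled slide collections.

Intended users: image-analysis researchers and computational-pathology
developers who need a transparent, fully deterministic feature-based
baseline (as opposed to a learned black box) for breast-tissue structure
quantification.

## The method in brief

Everything runs on the red channel of the RGB image, where the
hematoxylin-dark nuclei contrast most strongly with pinkish stroma.

1. **Nucleus scale.** Granulometry with disk structuring elements: the
   pattern spectrum
   `PS(λ) = [mes(γ_λ(I)) − mes(γ_{λ+Δ}(I))] / mes(I)` of the complemented
   channel peaks at the dominant nucleus radius `λ_n`; a secondary peak
   `λ_2` bounds the later size filter.
2. **Binarization.** Tiles of side `25·λ_n` are contrast-stretched from
   `[μ−2σ, μ]` to `[0, 255]` and thresholded per tile with Otsu's method
   (dark class = nuclei).
3. **Segmentation.** Components are partitioned by inscribed-disk scale;
   clumps are split by a watershed on the distance transform (suppression
   depth `λ_n/2`); elements are kept if their scale lies in
   `T_λ = [λ_n/2, λ_2]` and their MOR circularity is at least
   `T_c = μ_c − σ_c`.
4. **MOR circularity.** The mass of the boundary-radius distribution
   between the local minima flanking its mode — near 1 for disks, small
   for elongated or irregular shapes.
5. **Tubules.** Bright lumina candidates (area ≥ twice the mean nucleus
   area, intensity mode ≥ mean, not border-touching) grow by iterated
   dilation until the coefficient of variation of the region stops rising;
   the surrounding nuclei are then scored by
   `C_s = T_nuclei + l_cdis + l_θ + l_A`
   (nuclei-count penalty, hull-vs-lumina ellipse centroid distance and
   orientation difference, and ring asymmetry `(1−S)·100` with
   `S = min(N_u,N_l)/max(N_u,N_l)`). `C_s ≤ 60` classifies as tubule.
6. **Grading.** Nuclear pleomorphism is summarized by `Λ`, the eigenvalue
   sum of the (area, circularity) covariance on pooled-standardized
   features; grade classification draws random nucleus subsets per grade,
   represents each subset by its mean (area, intensity), and applies a
   deterministic 5-nearest-neighbour vote with stratified 10-fold
   cross-validation.

See the methods vignette (`vignettes/histograde-methods.Rmd`) for the full
account of parameters, numerical choices and limitations.

## Worked example

```r
library(histograde)

# a grade-1-like synthetic slide with exact ground truth
ph  <- generate_phantom(grade_preset("G1", seed = 42))
seg <- segment_nuclei(ph$rgb)
seg
#> Nuclei segmentation: 156 nuclei
#>   lambda_n = 3  lambda_2 = 4
#>   T_lambda = [ 2 , 4 ]  T_c = 0.905

evaluate_segmentation(seg$labels > 0, ph$nuclei_truth > 0)
#> # A tibble: 1 x 8
#>      tp    fp    fn     tn precision sensitivity accuracy   sdc
#>   <int> <int> <int>  <int>     <dbl>       <dbl>    <dbl> <dbl>
#> 1  8255   157  1900 137144     0.981       0.813    0.986 0.889

tub <- detect_tubules(ph$rgb, nuclei = seg)
tub
#> Tubule detection: 7645 lumina candidates, 7 tubules (Cs <= threshold)
head(dplyr::filter(tidy(tub), status == "assessed")[, c("label", "cs", "is_tubule")])
#> # A tibble: 6 x 3
#>   label      cs is_tubule
#>   <int>   <dbl> <lgl>
#> 1  1018 110     FALSE
#> 2  1302   0.402 TRUE
#> 3  2110  20.1   TRUE
#> 4  2367 110     FALSE
#> 5  3071 110     FALSE
#> 6  3911  30.5   TRUE
```

The granulometric scale settles at `λ_n = 3` (the planted nuclei have mean
radius 4.2 but elliptical minor axes nearer 3), segmentation recovers the
planted nuclei with Dice ≈ 0.89 and high precision, and the detector finds
all 7 planted tubules while every bright region without a nucleus ring —
the planted bare gaps and the white inter-tissue patches — scores
`C_s = 110 > 60` (degenerate hull: penalty 10 + asymmetry 100) and is
rejected. The numbers above are exactly what the calls print for this
seed.

A command-line front end is installed with the package
(`system.file("cli", "histograde", package = "histograde")`) with
subcommands `granulo`, `binarize`, `segment-nuclei`, `detect-tubules`,
`eval-seg`, `synth` and `run`.

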