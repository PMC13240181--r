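# Synthetic tissue-surrogate reference values (plausible lung/soft/bone
# materials; NOT vendor-measured data). reference_red is the relative
# electron density, reference_ean the effective atomic number under the
# exponent-3.1 convention.
name,reference_red,reference_ean,class
lung_inhale,0.28,7.70,lung
lung_exhale,0.45,7.60,lung
adipose,0.92,6.21,soft
breast,0.94,6.93,soft
brain,1.05,6.09,soft
muscle,1.04,7.64,soft
liver,1.05,7.74,soft
trabecular_bone,1.10,10.42,bone
cb2_30,1.28,10.90,bone
cb2_50,1.47,12.54,bone
cortical_bone,1.70,13.64,bone
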