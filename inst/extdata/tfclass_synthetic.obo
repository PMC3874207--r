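format-version: 1.2
ontology: tfclass-synthetic
subsetdef: superclass "TF superclass level"
subsetdef: class "TF class level"
subsetdef: family "TF family level"
subsetdef: subclass "TF subclass level"
subsetdef: gene "TF gene level"
subsetdef: factor_species "protein isoform level"

[Term]
id: TF:1
name: Basic domains
subset: superclass

[Term]
id: TF:2
name: Zinc-coordinating DNA-binding domains
subset: superclass

[Term]
id: TF:1.1
name: Basic leucine zipper factors (bZIP)
subset: class
is_a: TF:1

[Term]
id: TF:1.2
name: Basic helix-loop-helix factors (bHLH)
subset: class
is_a: TF:1

[Term]
id: TF:2.1
name: Nuclear receptors with C4 zinc fingers
subset: class
is_a: TF:2

[Term]
id: TF:1.1.1
name: Jun-related factors
subset: family
is_a: TF:1.1

[Term]
id: TF:1.2.1
name: Tal-related factors
subset: family
is_a: TF:1.2

[Term]
id: TF:2.1.1
name: Steroid hormone receptors (NR3)
subset: family
is_a: TF:2.1

[Term]
id: TF:1.1.1.1
name: JUN
subset: gene
xref: EntrezGene:3725
is_a: TF:1.1.1

[Term]
id: TF:1.1.1.2
name: JUNB
subset: gene
xref: EntrezGene:3726
is_a: TF:1.1.1

[Term]
id: TF:1.2.1.1
name: TAL1
subset: gene
xref: EntrezGene:6886
is_a: TF:1.2.1

[Term]
id: TF:2.1.1.1
name: ESRRB
subset: gene
xref: EntrezGene:2103
is_a: TF:2.1.1

[Term]
id: TF:1.1.1.1.1
name: jun (isoform a)
subset: factor_species
is_a: TF:1.1.1.1
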