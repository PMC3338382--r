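# Genotype subset of the reference definitions, also provided as Turtle and
# RDF/XML fixtures for the OWL readers.

Ontology:
  dc:title "Bone dysplasia knowledge model: genotype subset"
  dc:creator "bdokit"
  dc:contributor ""
  dc:publisher ""
  version "1.5"

ExternalTerm: HP:HP_0000005
  Source: HP
  Label: "Mode of inheritance"

ExternalTerm: HP:HP_0000006
  Source: HP
  Label: "Autosomal dominant inheritance"
  Parent: HP:HP_0000005

ExternalTerm: HP:HP_0000118
  Source: HP
  Label: "Phenotypic abnormality"

ExternalTerm: HP:HP_0000238
  Source: HP
  Label: "Hydrocephalus"
  Parent: HP:HP_0000118

ExternalTerm: HP:HP_0002938
  Source: HP
  Label: "Lumbar hyperlordosis"
  Parent: HP:HP_0000118

ExternalTerm: HP:HP_0002968
  Source: HP
  Label: "Phenotypic feature 0002968"
  Parent: HP:HP_0000118

ExternalTerm: HP:HP_0003505
  Source: HP
  Label: "Phenotypic feature 0003505"
  Parent: HP:HP_0000118

ExternalTerm: NCI:Missense_Mutation
  Source: NCI
  Label: "Missense mutation"
  Parent: NCI:Mutation_Abnormality

ExternalTerm: NCI:Mutation_Abnormality
  Source: NCI
  Label: "Mutation abnormality"

ExternalTerm: REAMS:Abnormality
  Source: REAMS
  Label: "Radiographic abnormality"

Class: Bone_Dysplasia
  Pillar: dysplasia
  Label: "Bone Dysplasia"
  Description: "A genetic disorder that involves abnormal development of bones and connective tissues."
  SubClassOf: characterized_by only (REAMS:Abnormality or HP:HP_0000118 or Phenotypic_Composite or Gene_Mutation)
  SubClassOf: mode_of_inheritance only HP:HP_0000005

Class: Gene_Mutation
  Pillar: gene_mutation
  Label: "Gene Mutation"
  Description: "A change or alteration in a gene."
  SubClassOf: has_locus only Gene and has_locus some Gene
  SubClassOf: mutation_type only NCI:Mutation_Abnormality and mutation_type some NCI:Mutation_Abnormality

Class: Achondroplasia
  Pillar: dysplasia
  Label: "Achondroplasia"
  Parent: Bone_Dysplasia
  SubClassOf: characterized_by only (GM0000001 or GM0000361 or HP:HP_0000238 or HP:HP_0002938 or HP:HP_0002968 or HP:HP_0003505)
  SubClassOf: mode_of_inheritance only HP:HP_0000006 and mode_of_inheritance some HP:HP_0000006

Class: G0000001
  Pillar: gene
  Label: "FGFR3"
  Parent: Gene

Class: GM0000001
  Pillar: gene_mutation
  Label: "GM0000001"
  Parent: Gene_Mutation
  SubClassOf: has_locus only G0000001 and has_locus some G0000001
  SubClassOf: mutation_type only NCI:Missense_Mutation and mutation_type some NCI:Missense_Mutation
  Annotation: encoding "GLY380ARG, 1138 G-A"
  Annotation: offset "1138"
  Annotation: count "1"
  Annotation: original_content "G"
  Annotation: mutated_content "A"

Class: GM0000361
  Pillar: gene_mutation
  Label: "GM0000361"
  Parent: Gene_Mutation
  SubClassOf: has_locus only G0000001 and has_locus some G0000001
  SubClassOf: mutation_type only NCI:Missense_Mutation and mutation_type some NCI:Missense_Mutation
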