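# Example synonym-table config for read_synonym_table(): class labels map to
# the phrases that may name them in a prompt; templates carry one {} slot.
classes:
  glioma:
    - Glioma
    - Brain tumor
    - Neoplasm
  meningioma:
    - Meningioma
    - Meningeal tumor
templates:
  - "Segment the {} region"
  - "Identify the {}"
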