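# Generator lexicon: TARGET (targets of toxic effects)
lung
lungs
liver
kidney
spleen
brain
heart
skin
rats
mice
zebrafish
daphnia
lymphocytes
macrophages
fibroblasts
keratinocytes
neurons
hepatocytes
erythrocytes
gills
embryos
algae
earthworms
alveolar macrophages
human keratinocytes
bronchial epithelium
aquatic organisms
lung tissue
immune system
nervous system
epithelial cells
renal tubules
gut microbiota
human lung fibroblasts
rat alveolar epithelium
freshwater fish species
human dermal fibroblasts
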