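# Synthetic stand-in for an anatomy/organism term list (~50 terms).
# Not derived from any released ontology; for demonstration and testing
# of the dictionary baseline only. One term per line, '#' comments.
lung
lungs
liver
kidney
kidneys
spleen
brain
heart
skin
blood
bone
muscle
intestine
stomach
pancreas
thymus
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
platelets
monocytes
neutrophils
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
respiratory tract
cardiovascular system
human lung fibroblasts
rat alveolar epithelium
freshwater fish species
human dermal fibroblasts
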