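# Generator lexicon: NANO (nanoparticles, nanomaterials, nanodevices)
# One term per line; token lengths 1-3; disjoint from the other categories.
fullerene
buckminsterfullerene
TiO2
ZnO
CuO
SiO2
Fe3O4
CeO2
Al2O3
C60
MWCNTs
SWCNTs
dendrimers
liposomes
nanosilver
nanogold
graphene
ferrofluid
nanocapsules
nanoshells
nanorods
nanowires
titanium dioxide
zinc oxide
silver nanoparticles
gold nanoparticles
copper nanoparticles
silica nanoparticles
carbon nanotubes
carbon nanoparticles
quantum dots
polymeric micelles
iron oxide
carbon black
polystyrene nanospheres
nickel nanoparticles
alumina nanoparticles
cadmium telluride
PAMAM dendrimers
fullerene derivatives
titanium dioxide particles
titanium dioxide nanoparticles
zinc oxide nanoparticles
iron oxide nanoparticles
multiwalled carbon nanotubes
cerium oxide nanoparticles
amorphous silica nanoparticles
superparamagnetic iron oxide
polyamidoamine dendrimer conjugates
cadmium selenide dots
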