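# Synthetic stand-in for a nanoparticle ontology term list (~50 terms).
# Not derived from any released ontology; for demonstration and testing
# of the dictionary baseline only. One term per line, '#' comments.
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
nanotubes
nanospheres
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
cadmium selenide dots
magnetic nanoparticles
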