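# MEDLINE check tags: near-ubiquitous descriptors removed before network
# construction. Edit freely; one term per line, '#' starts a comment.
Humans
Animals
Male
Female
Adult
Middle Aged
Aged
Aged, 80 and over
Adolescent
Child
Child, Preschool
Infant
Infant, Newborn
Young Adult
Pregnancy
Mice
Rats
Cattle
Dogs
Cats
Rabbits
Guinea Pigs
Cricetinae
Swine
Chick Embryo
History, 15th Century
History, 16th Century
History, 17th Century
History, 18th Century
History, 19th Century
History, 20th Century
History, 21st Century
Comparative Study
In Vitro Techniques
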