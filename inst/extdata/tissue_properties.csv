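name,sos_mps,atten_db_per_m_mhz,density,bulk_modulus
water,1500,0.22,1000,2250000000
fat,1437,60,950,1961720550
skin,1613,120,1090,2835928210
muscle,1571,70,1070,2640803870
cartilage,1664,150,1100,3045785600
ligament,1690,110,1140,3255954000
bone_cortical,2900,690,1900,15979000000
bone_trabecular,1600,40,1150,2944000000
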