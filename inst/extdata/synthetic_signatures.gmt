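IMM01	synthetic immune-cell signature	IMM01_g01	IMM01_g02	IMM01_g03	IMM01_g04	IMM01_g05	IMM01_g06	IMM01_g07	IMM01_g08
IMM02	synthetic immune-cell signature	IMM02_g01	IMM02_g02	IMM02_g03	IMM02_g04	IMM02_g05	IMM02_g06	IMM02_g07	IMM02_g08
IMM03	synthetic immune-cell signature	IMM03_g01	IMM03_g02	IMM03_g03	IMM03_g04	IMM03_g05	IMM03_g06	IMM03_g07	IMM03_g08
IMM04	synthetic immune-cell signature	IMM04_g01	IMM04_g02	IMM04_g03	IMM04_g04	IMM04_g05	IMM04_g06	IMM04_g07	IMM04_g08
IMM05	synthetic immune-cell signature	IMM05_g01	IMM05_g02	IMM05_g03	IMM05_g04	IMM05_g05	IMM05_g06	IMM05_g07	IMM05_g08
IMM06	synthetic immune-cell signature	IMM06_g01	IMM06_g02	IMM06_g03	IMM06_g04	IMM06_g05	IMM06_g06	IMM06_g07	IMM06_g08
IMM07	synthetic immune-cell signature	IMM07_g01	IMM07_g02	IMM07_g03	IMM07_g04	IMM07_g05	IMM07_g06	IMM07_g07	IMM07_g08
IMM08	synthetic immune-cell signature	IMM08_g01	IMM08_g02	IMM08_g03	IMM08_g04	IMM08_g05	IMM08_g06	IMM08_g07	IMM08_g08
IMM09	synthetic immune-cell signature	IMM09_g01	IMM09_g02	IMM09_g03	IMM09_g04	IMM09_g05	IMM09_g06	IMM09_g07	IMM09_g08
IMM10	synthetic immune-cell signature	IMM10_g01	IMM10_g02	IMM10_g03	IMM10_g04	IMM10_g05	IMM10_g06	IMM10_g07	IMM10_g08
IMM11	synthetic immune-cell signature	IMM11_g01	IMM11_g02	IMM11_g03	IMM11_g04	IMM11_g05	IMM11_g06	IMM11_g07	IMM11_g08
IMM12	synthetic immune-cell signature	IMM12_g01	IMM12_g02	IMM12_g03	IMM12_g04	IMM12_g05	IMM12_g06	IMM12_g07	IMM12_g08
IMM13	synthetic immune-cell signature	IMM13_g01	IMM13_g02	IMM13_g03	IMM13_g04	IMM13_g05	IMM13_g06	IMM13_g07	IMM13_g08
IMM14	synthetic immune-cell signature	IMM14_g01	IMM14_g02	IMM14_g03	IMM14_g04	IMM14_g05	IMM14_g06	IMM14_g07	IMM14_g08
IMM15	synthetic immune-cell signature	IMM15_g01	IMM15_g02	IMM15_g03	IMM15_g04	IMM15_g05	IMM15_g06	IMM15_g07	IMM15_g08
IMM16	synthetic immune-cell signature	IMM16_g01	IMM16_g02	IMM16_g03	IMM16_g04	IMM16_g05	IMM16_g06	IMM16_g07	IMM16_g08
MHC_CLASS_I	synthetic MHC class I antigen-presentation gene set	HLA_A	HLA_B	HLA_C	B2M	TAP1	TAP2	NLRC5
LIVER_CONTAM	synthetic liver contamination gene set	CONTAM_liver_01	CONTAM_liver_02	CONTAM_liver_03	CONTAM_liver_04	CONTAM_liver_05	CONTAM_liver_06	CONTAM_liver_07	CONTAM_liver_08	CONTAM_liver_09	CONTAM_liver_10	CONTAM_liver_11	CONTAM_liver_12	CONTAM_liver_13	CONTAM_liver_14	CONTAM_liver_15	CONTAM_liver_16	CONTAM_liver_17	CONTAM_liver_18	CONTAM_liver_19	CONTAM_liver_20	CONTAM_liver_21	CONTAM_liver_22	CONTAM_liver_23	CONTAM_liver_24	CONTAM_liver_25	CONTAM_liver_26	CONTAM_liver_27	CONTAM_liver_28	CONTAM_liver_29	CONTAM_liver_30
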