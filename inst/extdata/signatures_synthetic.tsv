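signature_name	gene	set_role
sInv	INVS01	positive
sInv	INVS02	positive
sInv	INVS03	positive
sInv	INVS04	positive
sInv	INVS05	positive
sInv	INVS06	positive
sInv	INVS07	positive
sInv	INVS08	positive
sInv	INVS09	positive
sInv	INVS10	positive
sCSC	MMP1	positive
sCSC	CSCS01	positive
sCSC	CSCS02	positive
sCSC	CSCS03	positive
sCSC	CSCS04	positive
sCSC	CSCS05	positive
sCSC	CSCS06	positive
sCSC	CSCS07	positive
sCSC	CSCS08	positive
sCSC	CSCS09	positive
sCSC	CSCS10	positive
sCSC	CSCS11	positive
sCSC	CSCS12	positive
sCSC	CSCS13	positive
sCSC	CSCS14	positive
sCSC	CSCS15	positive
sCSC	CSCS16	positive
sCSC	CSCS17	positive
sCSC	CSCS18	positive
sCSC	CSCS19	positive
sAng	KDR	positive
sAng	CSPG4	positive
sAng	ANGS01	positive
sAng	ANGS02	positive
sAng	ANGS03	positive
sAng	ANGS04	positive
sAng	ANGS05	positive
sAng	ANGS06	positive
sAng	ANGS07	positive
sAng	ANGS08	positive
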