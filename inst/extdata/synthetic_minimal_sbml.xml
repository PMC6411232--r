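<?xml version="1.0" encoding="UTF-8"?>
<!-- synthetic minimal SBML L3 FBC fixture; hand-written for reader tests -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
  <model id="synthetic_minimal">
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="lb_minus_five" value="-5" constant="true"/>
      <parameter id="ub_inf" value="inf" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="glc_e" boundaryCondition="true" constant="false"/>
      <species id="pool_c" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="uptake" reversible="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pool_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="shuttle" reversible="true"
                fbc:lowerFluxBound="lb_minus_five" fbc:upperFluxBound="ub_ten">
        <listOfReactants>
          <speciesReference species="pool_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="biomass_synth" reversible="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="pool_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
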