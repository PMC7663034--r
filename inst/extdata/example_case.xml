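<?xml version="1.0" encoding="UTF-8"?>
<case id="example001">
  <tirads>4c</tirads>
  <mark>
    <points>
      <point x="94.354187154197078" y="61.344352733463523"/>
      <point x="93.939249633738967" y="56.535306682196435"/>
      <point x="94.297465374750871" y="51.139488953435759"/>
      <point x="92.610516744969516" y="46.122164943779936"/>
      <point x="88.775888424033013" y=" 42.46264877537353"/>
      <point x="85.160475496113435" y="38.781927306505068"/>
      <point x="82.193974584973574" y="33.720141395821713"/>
      <point x="78.243604036506724" y="28.745842903974946"/>
      <point x="72.763183871573204" y="26.042480478364681"/>
      <point x="66.699037743895161" y=" 25.40196201028666"/>
      <point x="60.582323583390504" y="24.935779804239459"/>
      <point x="54.017491975394407" y="23.962347146043307"/>
      <point x="47.262161254002336" y="24.568122991464911"/>
      <point x="42.263097165084154" y="29.213683838873862"/>
      <point x="40.036193211499182" y="36.432793753760286"/>
      <point x="38.008189483481303" y="42.190281381959409"/>
      <point x="34.012412934481745" y="45.981639872669831"/>
      <point x="31.330008121105202" y="50.800466483104906"/>
      <point x="33.775265706437651" y="57.022070266394479"/>
      <point x="37.722798605094937" y="62.162519079656718"/>
      <point x="36.891168404413094" y="66.371715446047233"/>
      <point x="33.382785053080013" y="71.633729055335934"/>
      <point x="34.549004067707585" y=" 76.50120608554964"/>
      <point x="39.970395553679431" y="79.015363357009818"/>
      <point x="42.304910145273105" y="82.859253886445444"/>
      <point x=" 40.82052355487734" y="91.624224327927777"/>
      <point x=" 42.43068923039219" y="99.897361362300316"/>
      <point x="48.959458677569728" y=" 101.2266460954117"/>
      <point x="55.505988623661139" y="100.79160535250688"/>
      <point x="61.063234253182884" y="105.99770681937471"/>
      <point x="68.091838650666716" y="110.76992979158112"/>
      <point x="74.565736879408263" y="106.37685602468724"/>
      <point x="78.419001701850206" y=" 97.96903927212054"/>
      <point x="82.603794494658302" y="93.772294700985512"/>
      <point x="87.780015837586816" y="91.355778942775146"/>
      <point x="90.271310757930493" y="86.044247167523196"/>
      <point x="90.226849932755229" y="79.758681285738248"/>
      <point x="91.731922533089147" y="75.204423996196965"/>
      <point x="94.767352765367164" y="71.103203078662418"/>
      <point x="95.656342246703048" y="66.213627091104613"/>
    </points>
  </mark>
</case>
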